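#' Classify a dendritic spine from its geometry
#'
#' Applies, in order, the three morphological rules used for hippocampal
#' interneuron spines:
#' \itemize{
#'   \item \strong{stubby}: protrusion length < 1 um and no neck observed;
#'   \item \strong{mushroom}: a discernible head whose maximum diameter is
#'     at least 1.5 times the average neck length, with total length
#'     < 1.5 um;
#'   \item \strong{thin}: length >= 1.5 um, or length between 1 and
#'     1.5 um without a discernible head.
#' }
#' Boundary semantics are fixed as: stubby strictly below 1 um; the
#' mushroom head ratio is inclusive ("at least" 1.5x); 1.5 um belongs to
#' thin. A record matching no rule gets `"unclassified"` with a message.
#'
#' @param length_um protrusion length (um).
#' @param head_diam_um maximum head diameter (um), `NA` when no head.
#' @param neck_len_um average neck length (um), `NA` when no neck.
#' @param head_discernible logical: a clear head-like structure is seen.
#' @param neck_present logical: a neck is observed.
#' @return one of `"stubby"`, `"mushroom"`, `"thin"`, `"unclassified"`.
#' @examples
#' classify_spine(0.8, neck_present = FALSE)                   # stubby
#' classify_spine(1.2, 0.6, 0.35, head_discernible = TRUE)     # mushroom
#' classify_spine(1.7)                                         # thin
#' @export
classify_spine <- function(length_um, head_diam_um = NA, neck_len_um = NA,
                           head_discernible = FALSE, neck_present = TRUE) {
  stopifnot(length_um >= 0)
  if (!is.na(head_diam_um) && !head_discernible) {
    stop("head_diam_um given but head_discernible is FALSE")
  }
  if (length_um < 1 && !neck_present) return("stubby")
  if (head_discernible && !is.na(head_diam_um) && !is.na(neck_len_um) &&
      head_diam_um >= 1.5 * neck_len_um && length_um < 1.5) {
    return("mushroom")
  }
  if (length_um >= 1.5 ||
      (length_um >= 1 && length_um < 1.5 && !head_discernible)) {
    return("thin")
  }
  message("spine satisfies no classification rule; returning 'unclassified'")
  "unclassified"
}

#' Classify a table of spines
#'
#' Row-wise [classify_spine()] over a data.frame with columns
#' `length_um`, `head_diam_um`, `neck_len_um`, `head_discernible`,
#' `neck_present`.
#'
#' @param spines data.frame of spine records.
#' @return character vector of class labels.
#' @export
classify_spines <- function(spines) {
  vapply(seq_len(nrow(spines)), function(i) {
    classify_spine(spines$length_um[i], spines$head_diam_um[i],
                   spines$neck_len_um[i], spines$head_discernible[i],
                   spines$neck_present[i])
  }, character(1))
}

#' Generate class-conditional synthetic spines
#'
#' Samples spine geometries strictly inside the rule region of their
#' class (no record sits on a decision boundary such as length exactly
#' 1.0 or 1.5 um), so the classifier must agree with the generating label
#' on every record.
#'
#' @param n number of spines.
#' @param class_mix length-3 proportions (stubby, mushroom, thin),
#'   summing to 1.
#' @param seed integer seed.
#' @return data.frame with the geometry columns of [classify_spines()],
#'   `position_um` (distance from soma, 0-150 um), and `true_class`.
#' @export
generate_spines <- function(n, class_mix = c(1, 1, 1) / 3, seed = 1L) {
  stopifnot(length(class_mix) == 3L, abs(sum(class_mix) - 1) < 1e-9,
            all(class_mix >= 0), n >= 0)
  if (n == 0L) {
    return(data.frame(length_um = numeric(0), head_diam_um = numeric(0),
                      neck_len_um = numeric(0),
                      head_discernible = logical(0),
                      neck_present = logical(0), position_um = numeric(0),
                      true_class = character(0)))
  }
  with_seed(seed, {
    cls <- sample(c("stubby", "mushroom", "thin"), n, replace = TRUE,
                  prob = class_mix)
    len <- head <- neck <- numeric(n)
    hd <- np <- logical(n)
    for (i in seq_len(n)) {
      if (cls[i] == "stubby") {
        len[i] <- stats::runif(1, 0.2, 0.95)
        head[i] <- NA; neck[i] <- NA
        hd[i] <- FALSE; np[i] <- FALSE
      } else if (cls[i] == "mushroom") {
        len[i] <- stats::runif(1, 0.3, 1.45)
        neck[i] <- stats::runif(1, 0.2, 0.5)
        head[i] <- neck[i] * stats::runif(1, 1.6, 2.5)
        hd[i] <- TRUE; np[i] <- TRUE
      } else {
        len[i] <- stats::runif(1, 1.55, 3.0)
        neck[i] <- stats::runif(1, 0.3, 0.8)
        hd[i] <- stats::runif(1) < 0.5
        head[i] <- if (hd[i]) neck[i] * stats::runif(1, 0.5, 1.3) else NA
        np[i] <- TRUE
      }
    }
    data.frame(length_um = len, head_diam_um = head, neck_len_um = neck,
               head_discernible = hd, neck_present = np,
               position_um = stats::runif(n, 0, 150), true_class = cls)
  })
}

#' Spine densities along a dendrite
#'
#' Counts spines in half-open segments `[lo, hi)` of distance from the
#' soma (defaults: proximal 0-50, medial 50-100, distal 100-150 um) and
#' divides by the segment length; the final segment is closed at the top
#' so a spine at exactly the dendrite end is kept. The total density uses
#' the whole 0-150 um stretch. Positions beyond the last bound are
#' excluded with a message.
#'
#' @param spines data.frame with a `position_um` column.
#' @param segment_bounds_um segment boundary positions.
#' @return list with `segment` (data.frame: lo, hi, count, density) and
#'   `total_density` (spines per um over the full extent).
#' @export
spine_density <- function(spines, segment_bounds_um = c(0, 50, 100, 150)) {
  pos <- spines$position_um
  b <- segment_bounds_um
  stopifnot(length(b) >= 2L, all(diff(b) > 0))
  out <- sum(pos > b[length(b)] | pos < b[1])
  if (out > 0) {
    message(sprintf("spine_density: %d spines outside [%g, %g] excluded",
                    out, b[1], b[length(b)]))
  }
  lo <- b[-length(b)]
  hi <- b[-1]
  nseg <- length(lo)
  count <- vapply(seq_along(lo), function(i) {
    if (i < nseg) sum(pos >= lo[i] & pos < hi[i])
    else sum(pos >= lo[i] & pos <= hi[i])
  }, numeric(1))
  list(segment = data.frame(lo_um = lo, hi_um = hi, count = count,
                            density_per_um = count / (hi - lo)),
       total_density = sum(count) / (b[length(b)] - b[1]))
}

#' Detect en passant boutons along an axonal profile
#'
#' The axonal backbone brightness and width are taken as the medians over
#' the profile. Candidate boutons are local maxima of the brightness
#' profile; a candidate is accepted when it is at least twice as bright
#' and at least twice as wide as the backbone. Candidates flagged as
#' crossed by another axon (optional logical `crossing` column, a manual
#' exclusion) are rejected.
#'
#' @param profile data.frame with `position_um`, `brightness`, `width_um`
#'   (and optionally `crossing`), covering at least 10 um of axon.
#' @return list with `count`, `density_per_um`, `bouton_positions_um`,
#'   `backbone_brightness`, `backbone_width_um`.
#' @export
detect_boutons <- function(profile) {
  stopifnot(all(c("position_um", "brightness", "width_um") %in%
                  names(profile)))
  span <- diff(range(profile$position_um))
  if (span < 10) stop("axonal profile must cover at least 10 um")
  bb <- stats::median(profile$brightness)
  bw <- stats::median(profile$width_um)
  cand <- local_extrema(profile$brightness)$max
  ok <- profile$brightness[cand] >= 2 * bb & profile$width_um[cand] >= 2 * bw
  if ("crossing" %in% names(profile)) ok <- ok & !profile$crossing[cand]
  acc <- cand[ok]
  list(count = length(acc), density_per_um = length(acc) / span,
       bouton_positions_um = profile$position_um[acc],
       backbone_brightness = bb, backbone_width_um = bw)
}
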