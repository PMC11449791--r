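#' Normalized optical density of an image region
#'
#' Grey levels are converted to optical densities,
#' `OD = -log10(G / G_max)` with `G_max` the bit-depth maximum (zero grey
#' levels are clamped to 1 count with a message), averaged over the ROI,
#' and normalized by subtracting the mean OD of an internal white-matter
#' region.
#'
#' @param pixels numeric matrix of grey levels.
#' @param roi_mask logical matrix selecting the region of interest.
#' @param white_matter_mask logical matrix selecting the white-matter
#'   reference region.
#' @param bit_depth 8 or 16.
#' @return list with `od` (normalized OD), `od_roi`, `od_white`.
#' @export
optical_density <- function(pixels, roi_mask, white_matter_mask,
                            bit_depth = 8) {
  stopifnot(is.matrix(pixels), bit_depth %in% c(8, 16),
            identical(dim(pixels), dim(roi_mask)),
            identical(dim(pixels), dim(white_matter_mask)),
            any(roi_mask), any(white_matter_mask))
  gmax <- 2^bit_depth - 1
  if (any(pixels[roi_mask | white_matter_mask] <= 0)) {
    message("optical_density: zero grey levels clamped to 1 count")
  }
  od <- -log10(pmax(pixels, 1) / gmax)
  od_roi <- mean(od[roi_mask])
  od_white <- mean(od[white_matter_mask])
  list(od = od_roi - od_white, od_roi = od_roi, od_white = od_white)
}

#' Cavalieri volume estimate from section areas
#'
#' `volume = sum(areas) * thickness * series_factor`, in consistent
#' units: the area of the region in every analyzed section of a 1-in-
#' `series_factor` systematic series, multiplied by section thickness and
#' the series factor.
#'
#' @param areas numeric vector of per-section areas (>= 0).
#' @param thickness section thickness (same length unit as the areas).
#' @param series_factor the sampling series (default every 6th section).
#' @return the estimated volume.
#' @examples
#' cavalieri_volume(c(0.10, 0.12, 0.11), thickness = 0.05)   # 0.099 mm^3
#' @export
cavalieri_volume <- function(areas, thickness = 50, series_factor = 6) {
  if (length(areas) == 0L) return(0)
  if (any(areas < 0)) stop("section areas must be non-negative")
  sum(areas) * thickness * series_factor
}

#' Fractionator counts of labeled cells
#'
#' Counts cells per marker and per marker pair (co-localization), scaled
#' by the series factor: every labeled cell in the full sample area of a
#' 1-in-`series_factor` section series is counted.
#'
#' @param cells list of character vectors: the marker labels carried by
#'   each counted cell.
#' @param markers declared marker set; an undeclared label in `cells` is
#'   an error.
#' @param series_factor sampling series factor.
#' @return list with `counts` (named, scaled per-marker totals) and
#'   `co_counts` (named matrix of scaled pairwise co-localization
#'   totals).
#' @examples
#' cells <- c(rep(list("PV"), 6), rep(list("PNN"), 2),
#'            rep(list(c("PV", "PNN")), 4))
#' fractionator_count(cells, c("PV", "PNN"))$counts   # PV 60, PNN 36
#' @export
fractionator_count <- function(cells, markers, series_factor = 6) {
  labs <- unique(unlist(cells))
  if (length(setdiff(labs, markers)) > 0L) {
    stop("unknown marker label: ", paste(setdiff(labs, markers),
                                         collapse = ", "))
  }
  has <- vapply(markers, function(m) {
    vapply(cells, function(s) m %in% s, logical(1))
  }, logical(length(cells)))
  has <- matrix(has, nrow = length(cells), ncol = length(markers),
                dimnames = list(NULL, markers))
  counts <- colSums(has) * series_factor
  co <- crossprod(has) * series_factor
  list(counts = counts, co_counts = co)
}

#' Normalized isotope ratio from ion counts
#'
#' Per-ROI ratio `n15 / n14`; the result is the mean ratio over the
#' marker-positive ROIs divided by the mean ratio over the negative ROIs.
#'
#' @param measurements data.frame with columns `n15`, `n14` (counts,
#'   `n14 > 0`) and `label` (`"positive"` or `"negative"`).
#' @return list with `ratio` (normalized), `mean_positive`,
#'   `mean_negative`.
#' @export
isotope_ratio <- function(measurements) {
  stopifnot(all(c("n15", "n14", "label") %in% names(measurements)))
  if (any(measurements$n14 <= 0)) stop("n14 counts must be positive")
  pos <- measurements$label == "positive"
  neg <- measurements$label == "negative"
  if (!any(pos) || !any(neg)) {
    stop("need at least one positive and one negative ROI")
  }
  r <- measurements$n15 / measurements$n14
  list(ratio = mean(r[pos]) / mean(r[neg]),
       mean_positive = mean(r[pos]), mean_negative = mean(r[neg]))
}

#' Co-expression percentage among marker-positive cells
#'
#' Percentage of cells carrying `base_marker` that also carry
#' `probe_marker` (e.g. Epor+ among Gad1+ interneurons).
#'
#' @param cells list of character vectors of marker labels per cell.
#' @param base_marker the reference population marker.
#' @param probe_marker the probed marker.
#' @return percentage in `[0, 100]`.
#' @export
coexpression_percent <- function(cells, base_marker, probe_marker) {
  base <- vapply(cells, function(s) base_marker %in% s, logical(1))
  if (!any(base)) stop("no cells carry the base marker")
  both <- vapply(cells, function(s) {
    base_marker %in% s && probe_marker %in% s
  }, logical(1))
  100 * sum(both) / sum(base)
}
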