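#' Sholl analysis of a neuron morphology
#'
#' Counts intersections of the dendritic tree with concentric spheres of
#' radius `step_um, 2*step_um, ...` (up to the maximum node distance)
#' centered on the soma. Distances are Euclidean in 3D; within each
#' parent-child segment the position is linearly interpolated, so a
#' crossing is a root of the quadratic `|p(t) - soma|^2 = r^2` with
#' `t` in the half-open interval `(0, 1]` (a node exactly on a sphere
#' counts once, for the segment that ends on it; tangencies are ignored).
#'
#' The sphere step is 20 um for GAD-EGFP interneurons and 10 um for PV+
#' cells in the intended application.
#'
#' @param tree a [neuron_tree()].
#' @param step_um sphere spacing in micrometers.
#' @return object of class `sholl_profile`: list with `radii_um`,
#'   `intersections`, `step_um`, `total`.
#' @examples
#' cable <- generate_neuron_tree(0, step_um = 10, seed = 1)
#' sholl(cable, step_um = 20)$total   # 5
#' @export
sholl <- function(tree, step_um) {
  stopifnot(inherits(tree, "neuron_tree"), step_um > 0)
  nd <- tree$nodes
  soma <- as.numeric(nd[match(tree$soma_id, nd$id), c("x", "y", "z")])
  P <- as.matrix(nd[, c("x", "y", "z")])
  P <- sweep(P, 2L, soma)
  dist <- sqrt(rowSums(P^2))
  rmax <- max(dist)
  if (rmax < step_um) {
    return(structure(list(radii_um = numeric(0),
                          intersections = integer(0),
                          step_um = step_um, total = 0L),
                     class = "sholl_profile"))
  }
  radii <- seq(step_um, rmax, by = step_um)
  child <- which(nd$parent != -1)
  pidx <- match(nd$parent[child], nd$id)
  counts <- integer(length(radii))
  eps <- 1e-9
  for (k in seq_along(child)) {
    p1 <- P[pidx[k], ]
    p2 <- P[child[k], ]
    v <- p2 - p1
    a <- sum(v^2)
    if (a == 0) next
    d1 <- sqrt(sum(p1^2))
    d2 <- sqrt(sum(p2^2))
    # distance along the segment is a convex function of t, so the
    # crossing count per sphere follows from the endpoint distances and
    # the interior minimum; a node exactly on a sphere counts once, for
    # the segment that ends on it
    tstar <- -sum(v * p1) / a
    dmin <- if (tstar > 0 && tstar < 1) {
      sqrt(sum((p1 + tstar * v)^2))
    } else {
      min(d1, d2)
    }
    for (j in seq_along(radii)) {
      r <- radii[j]
      tol <- eps * (r + 1)
      s1 <- d1 - r
      s2 <- d2 - r
      add <- if (abs(s2) <= tol) {
        1L                                   # child node on the sphere
      } else if (abs(s1) <= tol) {
        0L                                   # counted by the parent segment
      } else if (s1 * s2 < 0) {
        1L                                   # transversal crossing
      } else if (s1 > 0 && s2 > 0 && dmin < r - tol) {
        2L                                   # interior dip through the sphere
      } else {
        0L                                   # same side (tangency ignored)
      }
      counts[j] <- counts[j] + add
    }
  }
  structure(list(radii_um = radii, intersections = counts,
                 step_um = step_um, total = sum(counts)),
            class = "sholl_profile")
}

#' @export
print.sholl_profile <- function(x, ...) {
  cat(sprintf("<sholl_profile> step %g um, %d spheres, %d intersections\n",
              x$step_um, length(x$radii_um), x$total))
  invisible(x)
}
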