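# Brute-force Sholl oracle: dense sampling of every parent-child segment,
# counting sign changes of (distance - radius), with the shared
# convention that a node exactly on a sphere counts once, for the segment
# ending on it.
sholl_brute_force <- function(tree, step_um, nsamp = 4000) {
  nd <- tree$nodes
  soma <- as.numeric(nd[match(tree$soma_id, nd$id), c("x", "y", "z")])
  child <- which(nd$parent != -1)
  pidx <- match(nd$parent[child], nd$id)
  d_nodes <- sqrt((nd$x - soma[1])^2 + (nd$y - soma[2])^2 +
                    (nd$z - soma[3])^2)
  if (max(d_nodes) < step_um) return(integer(0))
  radii <- seq(step_um, max(d_nodes), by = step_um)
  counts <- integer(length(radii))
  for (k in seq_along(child)) {
    p1 <- as.numeric(nd[pidx[k], c("x", "y", "z")]) - soma
    p2 <- as.numeric(nd[child[k], c("x", "y", "z")]) - soma
    ts <- seq(0, 1, length.out = nsamp)
    dd <- sqrt(colSums((outer(p1, rep(1, nsamp)) + outer(p2 - p1, ts))^2))
    d1 <- dd[1]
    d2 <- dd[nsamp]
    for (j in seq_along(radii)) {
      r <- radii[j]
      tol <- 1e-9 * (r + 1)
      counts[j] <- counts[j] + if (abs(d2 - r) <= tol) {
        1L
      } else if (abs(d1 - r) <= tol) {
        0L
      } else {
        sum(abs(diff(dd > r)) > 0)
      }
    }
  }
  counts
}

# band signals constructed directly, for detector-semantics tests
make_bands <- function(theta, low = NULL, fs = 1000) {
  n <- length(theta)
  if (is.null(low)) low <- numeric(n)
  structure(list(low = low, theta = theta, supra = numeric(n),
                 residual = numeric(n), fs_hz = fs, band = "theta"),
            class = "band_signals")
}

# amplitude of a sampled sinusoid from the RMS of its central part
central_amplitude <- function(x, trim = 0.1) {
  n <- length(x)
  i <- seq(floor(n * trim) + 1L, ceiling(n * (1 - trim)))
  sqrt(2) * sqrt(mean(x[i]^2))
}
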