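#' Empirical mode decomposition by classical sifting
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) using the
#' Hilbert-Huang sifting procedure: cubic-spline envelopes are fitted
#' through the local maxima and minima (with mirror extension of the
#' extrema at both ends to limit end swings), the envelope mean is
#' subtracted, and the step is iterated until the Cauchy convergence
#' criterion falls below `stop_sd` or `max_sift` iterations are reached.
#' IMF extraction stops when the running residual is monotonic (fewer than
#' two maxima or two minima) or `max_imfs` have been extracted.
#'
#' The decomposition is complete by construction: `rowSums` of the IMFs
#' plus the residual reproduces the input to floating-point accuracy.
#'
#' @param x numeric series, length >= 64, all finite.
#' @param max_imfs maximum number of IMFs to extract.
#' @param stop_method sifting stop rule. `"rilling"` (default) stops when
#'   the envelope mean is pointwise small relative to the envelope
#'   amplitude (|m|/a < 0.05 on at least 95% of samples and < 0.5
#'   everywhere); `"cauchy"` stops when
#'   `sum((h_prev - h)^2) / sum(h_prev^2) < stop_sd`. The Rilling rule
#'   adapts locally and avoids the mode mixing an aggregate energy
#'   criterion permits on signals with a dominant oscillation.
#' @param stop_sd Cauchy stopping threshold (used by
#'   `stop_method = "cauchy"`).
#' @param max_sift maximum sifting iterations per IMF.
#' @param fs_hz optional sampling rate; when given, a mean instantaneous
#'   frequency is computed per IMF and stored in `mean_if_hz`.
#' @return an object of class `imf_set`: list with `imfs` (matrix, one
#'   column per IMF; zero columns when none), `residual`, `mean_if_hz`
#'   (numeric per IMF, `NA` without `fs_hz`) and `fs_hz`.
#' @examples
#' t <- seq(0, 2, by = 1 / 200)
#' dec <- emd(sin(2 * pi * 8 * t) + 0.5 * sin(2 * pi * 40 * t), fs_hz = 200)
#' ncol(dec$imfs)
#' @export
emd <- function(x, max_imfs = 12L, stop_method = c("rilling", "cauchy"),
                stop_sd = 0.2, max_sift = 100L, fs_hz = NULL) {
  if (length(x) < 64L) stop("series must have at least 64 samples")
  if (!all(is.finite(x))) stop("series must be finite")
  stop_method <- match.arg(stop_method)
  n <- length(x)
  residual <- as.numeric(x)
  rms_x <- sqrt(mean(residual^2))
  imfs <- vector("list", max_imfs)
  k <- 0L
  while (k < max_imfs) {
    # a residual at numerical-noise level carries no further modes;
    # sifting it would only fit splines through rounding error
    if (sqrt(mean(residual^2)) < 1e-10 * rms_x) break
    ext <- local_extrema(residual)
    if (length(ext$max) < 2L || length(ext$min) < 2L) break
    h <- .sift_imf(residual, if (stop_method == "rilling") 0L else 1L,
                   stop_sd, as.integer(max_sift))
    if (is.null(h)) break
    k <- k + 1L
    imfs[[k]] <- h
    residual <- residual - h
  }
  imf_mat <- if (k > 0L) {
    do.call(cbind, imfs[seq_len(k)])
  } else {
    matrix(numeric(0), nrow = n, ncol = 0)
  }
  mean_if <- rep(NA_real_, k)
  if (!is.null(fs_hz) && k > 0L) {
    mean_if <- apply(imf_mat, 2L, function(col) {
      if (stats::sd(col) == 0) return(NA_real_)
      mean_instantaneous_frequency(col, fs_hz)
    })
  }
  structure(
    list(imfs = imf_mat, residual = residual, mean_if_hz = mean_if,
         fs_hz = fs_hz),
    class = "imf_set"
  )
}

#' Mean instantaneous frequency of an oscillatory component
#'
#' The analytic signal is formed via the Hilbert transform; instantaneous
#' frequency is the (unwrapped) phase derivative. The mean is
#' amplitude-weighted by default, which down-weights low-amplitude stretches
#' where phase is dominated by noise; samples with negative instantaneous
#' frequency are excluded.
#'
#' @param imf numeric series (one IMF), non-constant.
#' @param fs sampling rate in Hz.
#' @param weighted amplitude-weight the mean (default) or plain mean.
#' @return mean instantaneous frequency in Hz.
#' @export
mean_instantaneous_frequency <- function(imf, fs, weighted = TRUE) {
  if (stats::sd(imf) == 0) stop("instantaneous frequency undefined for a constant series")
  z <- analytic_signal(imf)
  phi <- Arg(z)
  dphi <- diff(phi)
  dphi <- dphi - 2 * pi * round(dphi / (2 * pi))
  inst_f <- dphi * fs / (2 * pi)
  amp <- Mod(z)
  w <- (amp[-length(amp)] + amp[-1]) / 2
  keep <- inst_f > 0
  if (!any(keep)) stop("no positive instantaneous frequencies")
  if (weighted) {
    sum(inst_f[keep] * w[keep]) / sum(w[keep])
  } else {
    mean(inst_f[keep])
  }
}

#' Combine IMFs into low / theta / supra-theta band signals
#'
#' Each IMF is assigned to exactly one band by its mean instantaneous
#' frequency: low (< `theta_lo`), theta (`[theta_lo, theta_hi)`), or
#' supra-theta (>= `theta_hi`). Bands with no IMF are zero series. The
#' residual is carried through so that `low + theta + supra + residual`
#' reconstructs the decomposed signal.
#'
#' @param imfset an `imf_set` from [emd()] (decomposed with `fs_hz` set).
#' @param theta_lo,theta_hi theta band edges in Hz.
#' @return an object of class `band_signals`: list with `low`, `theta`,
#'   `supra`, `residual`, `fs_hz`, and `band` (the per-IMF assignment).
#' @export
band_combine <- function(imfset, theta_lo = 5, theta_hi = 12) {
  stopifnot(inherits(imfset, "imf_set"))
  if (is.null(imfset$fs_hz)) stop("imf_set must carry fs_hz for band assignment")
  n <- length(imfset$residual)
  k <- ncol(imfset$imfs)
  zero <- numeric(n)
  band <- character(0)
  low <- theta <- supra <- zero
  if (k > 0L) {
    mif <- imfset$mean_if_hz
    band <- ifelse(mif < theta_lo, "low",
                   ifelse(mif < theta_hi, "theta", "supra"))
    for (j in seq_len(k)) {
      switch(band[j],
             low   = low   <- low   + imfset$imfs[, j],
             theta = theta <- theta + imfset$imfs[, j],
             supra = supra <- supra + imfset$imfs[, j])
    }
  }
  structure(
    list(low = low, theta = theta, supra = supra,
         residual = imfset$residual, fs_hz = imfset$fs_hz, band = band),
    class = "band_signals"
  )
}
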