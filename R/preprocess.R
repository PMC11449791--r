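#' Downsample a recording with Fourier anti-aliasing
#'
#' Resamples the LFP trace onto `round(n * target_fs / fs)` samples using
#' frequency-domain resampling: the spectrum is truncated at the new
#' Nyquist and additionally zeroed above `0.45 * target_fs` (the
#' anti-alias cutoff), then inverse-transformed on the new grid. The
#' operation is exactly zero-phase, handles non-integer rate ratios, and
#' preserves duration to within one sample. The velocity trace is left
#' untouched.
#'
#' @param rec a [recording()].
#' @param target_fs target sampling rate in Hz (<= `rec$fs_hz`).
#' @return a `recording` at `target_fs`.
#' @export
downsample <- function(rec, target_fs) {
  stopifnot(inherits(rec, "recording"))
  if (target_fs > rec$fs_hz) stop("target_fs must not exceed the current rate")
  if (target_fs == rec$fs_hz) return(rec)
  x <- rec$lfp
  n <- length(x)
  m <- round(n * target_fs / rec$fs_hz)
  X <- stats::fft(x)
  cutoff <- 0.45 * target_fs
  kcut <- floor(cutoff * n / rec$fs_hz)      # highest retained bin index
  kkeep <- min(kcut, floor((m - 1) / 2))
  Y <- complex(m)
  Y[1] <- X[1]
  if (kkeep >= 1) {
    Y[2:(kkeep + 1)] <- X[2:(kkeep + 1)]
    Y[(m - kkeep + 1):m] <- X[(n - kkeep + 1):n]
  }
  y <- Re(stats::fft(Y, inverse = TRUE)) / n
  out <- rec
  out$lfp <- y
  out$fs_hz <- target_fs
  out$meta$downsampled_from_hz <- rec$fs_hz
  out
}

#' Notch-filter mains contamination and its harmonics
#'
#' Zero-phase (forward-backward) Butterworth bandstop of width
#' `2 * bw_hz` centered on `base_hz` and each harmonic below
#' `0.9 *` Nyquist. Harmonics at or above that limit are skipped with a
#' message. The filter is an order-4 Butterworth bandstop (two poles per
#' band edge) applied with `signal::filtfilt`, so the passband is
#' phase-distortion free.
#'
#' @param rec a [recording()].
#' @param base_hz mains frequency (default 50).
#' @param n_harmonics number of harmonics to remove including the
#'   fundamental; `NULL` removes every integer multiple below
#'   `0.9 *` Nyquist.
#' @param bw_hz half-width of each stopband in Hz.
#' @return a filtered `recording`; the stopbands actually applied are
#'   recorded in `meta$notch_bands_hz`.
#' @export
notch_filter <- function(rec, base_hz = 50, n_harmonics = NULL, bw_hz = 1) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$fs_hz / 2
  if (base_hz >= nyq) stop("base_hz must be below the Nyquist frequency")
  kmax <- floor(0.9 * nyq / base_hz)
  ks <- seq_len(if (is.null(n_harmonics)) kmax else n_harmonics)
  x <- rec$lfp
  # odd-reflection padding suppresses the forward-backward filter's edge
  # transients; a stopband of half-width bw rings for ~1/bw seconds, so
  # the pad scales with the inverse bandwidth
  npad <- min(length(x) - 1L, round(max(2, 3 / bw_hz) * rec$fs_hz))
  bands <- NULL
  for (k in ks) {
    f0 <- k * base_hz
    if (f0 >= 0.9 * nyq) {
      message(sprintf("notch: skipping %g Hz harmonic (>= 0.9 x Nyquist)", f0))
      next
    }
    w <- c(f0 - bw_hz, f0 + bw_hz) / nyq
    flt <- signal::butter(2, w, type = "stop")
    left <- 2 * x[1] - x[(npad + 1L):2]
    right <- 2 * x[length(x)] - x[(length(x) - 1L):(length(x) - npad)]
    xf <- signal::filtfilt(flt, c(left, x, right))
    x <- xf[(npad + 1L):(npad + length(x))]
    bands <- rbind(bands, c(f0 - bw_hz, f0 + bw_hz))
  }
  out <- rec
  out$lfp <- x
  out$meta$notch_bands_hz <- bands
  out
}

#' z-score a recording
#'
#' Centers and scales the LFP trace to zero mean and unit standard
#' deviation using the sample (n-1) convention.
#'
#' @param rec a [recording()].
#' @return a normalized `recording`.
#' @export
zscore <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  s <- stats::sd(rec$lfp)
  if (!is.finite(s) || s == 0) stop("cannot z-score a constant signal")
  out <- rec
  out$lfp <- (rec$lfp - mean(rec$lfp)) / s
  out
}

#' Full signal-conditioning pipeline
#'
#' Applies, in order, [downsample()] to `target_fs`, [notch_filter()] at
#' `base_hz` and its harmonics, and [zscore()].
#'
#' @inheritParams downsample
#' @inheritParams notch_filter
#' @return a conditioned `recording`.
#' @export
preprocess <- function(rec, target_fs = 1000, base_hz = 50,
                       n_harmonics = NULL, bw_hz = 1) {
  zscore(notch_filter(downsample(rec, target_fs),
                      base_hz = base_hz, n_harmonics = n_harmonics,
                      bw_hz = bw_hz))
}
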