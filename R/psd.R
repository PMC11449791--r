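#' Welch power spectral density
#'
#' Averaged modified periodograms: Hamming-tapered segments of
#' `window_s` seconds with `overlap` fractional overlap, each zero-padded
#' (or natively resolved) onto a frequency grid of exactly
#' `resolution_hz` spacing. One-sided density scaling, so that the
#' integral of the PSD over frequency equals the series variance
#' (Parseval). Segment means are removed before tapering. A series
#' shorter than one window is analyzed as a single zero-padded segment.
#'
#' @param x numeric series.
#' @param fs sampling rate, Hz.
#' @param window_s segment length in seconds (default 5).
#' @param overlap fractional overlap between segments (default 0.5).
#' @param resolution_hz frequency-grid spacing (default 0.2).
#' @return object of class `psd_estimate`: list with `freq_hz`, `power`,
#'   and the method parameters.
#' @export
welch_psd <- function(x, fs, window_s = 5, overlap = 0.5,
                      resolution_hz = 0.2) {
  if (length(x) == 0L) stop("empty series")
  nfft <- round(fs / resolution_hz)
  nwin <- min(round(window_s * fs), length(x))
  if (nwin > nfft) nwin <- nfft
  w <- hamming_window(nwin)
  hop <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, max(1L, length(x) - nwin + 1L), by = hop)
  acc <- numeric(floor(nfft / 2) + 1L)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nwin - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(c(seg, numeric(nfft - nwin)))
    P <- Mod(X[seq_len(floor(nfft / 2) + 1L)])^2
    acc <- acc + P
  }
  acc <- acc / length(starts)
  scale <- 1 / (fs * sum(w^2))
  pw <- 2 * acc * scale
  pw[1] <- acc[1] * scale
  if (nfft %% 2 == 0) pw[length(pw)] <- acc[length(acc)] * scale
  structure(
    list(freq_hz = (seq_along(pw) - 1L) * fs / nfft, power = pw,
         window_s = window_s, overlap = overlap,
         resolution_hz = fs / nfft, fs_hz = fs, n_segments = length(starts)),
    class = "psd_estimate"
  )
}

hamming_window <- function(n) {
  if (n == 1L) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))
}

#' Pooled PSD over all theta cycles
#'
#' Concatenates the valley-to-valley snippets of every detected cycle in
#' time order and estimates the Welch PSD of the concatenation. Adjacent
#' snippets are spliced with a `taper_ms` cosine cross-fade to suppress
#' splice transients, and the record is first high-passed at `hp_hz`
#' ([spectral_highpass()]): content far below the fit band cannot inform
#' the in-band slope but its (large) amplitude turns every splice into a
#' broadband step artifact. Set `hp_hz = 0` to pool the raw snippets.
#'
#' @param rec a conditioned [recording()].
#' @param cycles a `theta_cycles` data.frame from [detect_cycles()].
#' @param taper_ms cross-fade length at each splice, ms.
#' @param hp_hz spectral high-pass cutoff applied before pooling.
#' @param repair_hz optional two-column matrix of notched bands to
#'   interpolate across first (see [spectral_repair()]).
#' @inheritParams welch_psd
#' @return a `psd_estimate`.
#' @export
pooled_theta_psd <- function(rec, cycles, taper_ms = 5, hp_hz = 15,
                             repair_hz = NULL, window_s = 5, overlap = 0.5,
                             resolution_hz = 0.2) {
  stopifnot(inherits(rec, "recording"))
  if (nrow(cycles) == 0L) stop("no theta cycles to pool")
  x <- spectral_repair(rec$lfp, rec$fs_hz, repair_hz)
  x <- spectral_highpass(x, rec$fs_hz, hp_hz)
  ntap <- round(taper_ms / 1000 * rec$fs_hz)
  snippets <- lapply(seq_len(nrow(cycles)), function(i) {
    x[cycles$valley_left_idx[i]:cycles$valley_right_idx[i]]
  })
  welch_psd(crossfade_concat(snippets, ntap), rec$fs_hz,
            window_s = window_s, overlap = overlap,
            resolution_hz = resolution_hz)
}

# splice snippets with a cosine cross-fade of ntap samples
crossfade_concat <- function(snippets, ntap) {
  if (length(snippets) == 1L) return(snippets[[1]])
  k <- min(ntap, min(lengths(snippets)) %/% 2L)
  if (k < 1L) return(unlist(snippets, use.names = FALSE))
  w <- 0.5 * (1 - cos(pi * (seq_len(k) - 0.5) / k))
  out <- snippets[[1]]
  for (i in 2:length(snippets)) {
    s <- snippets[[i]]
    m <- length(out)
    out <- c(out[seq_len(m - k)],
             out[(m - k + 1L):m] * (1 - w) + s[seq_len(k)] * w,
             s[(k + 1L):length(s)])
  }
  out
}

#' Single-cycle periodogram on a fixed-resolution grid
#'
#' Hamming-windowed periodogram of one valley-to-valley snippet,
#' zero-padded to a `resolution_hz` frequency grid. A window of one theta
#' cycle (~125 ms) cannot reject an oscillation 30-40 dB above the
#' in-band floor by tapering alone, so [cycle_slopes()] replaces the
#' theta-band and notch-band spectral content of the record by
#' interpolated background ([spectral_repair()]) before snipping;
#' `hp_hz > 0` optionally removes everything below that cutoff instead.
#'
#' @param rec a conditioned [recording()].
#' @param cycle one row of a `theta_cycles` data.frame.
#' @param hp_hz optional spectral high-pass cutoff (0 = raw snippet).
#' @inheritParams welch_psd
#' @return a `psd_estimate`.
#' @export
cycle_psd <- function(rec, cycle, resolution_hz = 0.2, hp_hz = 0) {
  stopifnot(inherits(rec, "recording"))
  i0 <- cycle$valley_left_idx
  i1 <- cycle$valley_right_idx
  if ((i1 - i0) / rec$fs_hz * 1000 < 71) {
    stop("cycle snippet shorter than 71 ms violates the cycle contract")
  }
  x <- spectral_highpass(rec$lfp, rec$fs_hz, hp_hz)
  seg <- x[i0:i1]
  welch_psd(seg, rec$fs_hz, window_s = length(seg) / rec$fs_hz,
            overlap = 0, resolution_hz = resolution_hz)
}

#' Fit the log-log spectral slope over a frequency band
#'
#' Ordinary least squares of `log10(power)` on `log10(freq)` over the grid
#' points with `band[1] <= f <= band[2]` (both endpoints inclusive).
#' Frequencies inside any `exclude_hz` range (e.g. notch stopbands) are
#' omitted from the fit; non-positive powers are dropped with a message.
#'
#' @param psd a `psd_estimate`.
#' @param band two-element fit band in Hz (default `c(30, 50)`).
#' @param exclude_hz optional two-column matrix of frequency ranges to
#'   exclude (e.g. `meta$notch_bands_hz` of a notch-filtered recording).
#' @return object of class `slope_fit`: list with intercept `a`, slope
#'   `b`, `band_hz`, `r2`, `n_points`, `residual_var`.
#' @examples
#' f <- seq(30, 50, by = 0.2)
#' psd <- structure(list(freq_hz = f, power = 10 * f^-2),
#'                  class = "psd_estimate")
#' fit_slope(psd)$b   # -2
#' @export
fit_slope <- function(psd, band = c(30, 50), exclude_hz = NULL) {
  stopifnot(inherits(psd, "psd_estimate"), length(band) == 2L)
  sel <- psd$freq_hz >= band[1] & psd$freq_hz <= band[2]
  if (!is.null(exclude_hz)) {
    ex <- matrix(as.numeric(exclude_hz), ncol = 2)
    for (i in seq_len(nrow(ex))) {
      sel <- sel & !(psd$freq_hz >= ex[i, 1] & psd$freq_hz <= ex[i, 2])
    }
  }
  f <- psd$freq_hz[sel]
  p <- psd$power[sel]
  bad <- p <= 0
  if (any(bad)) {
    message(sprintf("fit_slope: dropping %d non-positive power values", sum(bad)))
    f <- f[!bad]; p <- p[!bad]
  }
  if (length(f) < 3L) stop("fewer than 3 usable grid points in the fit band")
  lx <- log10(f)
  ly <- log10(p)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  res <- fit$residuals
  b <- unname(fit$coefficients[2])
  a <- unname(fit$coefficients[1])
  r2 <- 1 - sum(res^2) / sum((ly - mean(ly))^2)
  structure(
    list(a = a, b = b, band_hz = band, r2 = r2, n_points = length(f),
         residual_var = sum(res^2) / (length(f) - 2L)),
    class = "slope_fit"
  )
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("<slope_fit> b = %.4f (a = %.4f, R2 = %.3f, n = %d, band %g-%g Hz)\n",
              x$b, x$a, x$r2, x$n_points, x$band_hz[1], x$band_hz[2]))
  invisible(x)
}

#' Per-cycle spectral slopes
#'
#' Computes [cycle_psd()] and [fit_slope()] for every detected cycle and
#' returns the cycles table with `slope_30_50` filled. The high-pass is
#' applied once to the whole record.
#'
#' @inheritParams pooled_theta_psd
#' @inheritParams fit_slope
#' @param hp_hz optional spectral high-pass cutoff (0 = none; the
#'   default path relies on `repair_hz` instead, which preserves full
#'   spectral support and avoids the small steep bias a hard cutoff
#'   induces in very short windows).
#' @param repair_hz two-column matrix of bands to interpolate across
#'   before snipping (default: the 4-13.5 Hz theta region; the pipeline
#'   adds the notch stopbands). See [spectral_repair()].
#' @return the `theta_cycles` data.frame with the slope column filled.
#' @export
cycle_slopes <- function(rec, cycles, band = c(30, 50), exclude_hz = NULL,
                         hp_hz = 0, repair_hz = rbind(c(4, 13.5))) {
  if (nrow(cycles) == 0L) return(cycles)
  hp_rec <- rec
  hp_rec$lfp <- spectral_highpass(
    spectral_repair(rec$lfp, rec$fs_hz, repair_hz), rec$fs_hz, hp_hz)
  cycles$slope_30_50 <- vapply(seq_len(nrow(cycles)), function(i) {
    psd <- cycle_psd(hp_rec, cycles[i, ], hp_hz = 0)
    fit_slope(psd, band = band, exclude_hz = exclude_hz)$b
  }, numeric(1))
  cycles
}

#' Theta-cycle spectral-slope pipeline
#'
#' Runs the full estimator on one recording: signal conditioning
#' ([preprocess()], with a narrow +/- 0.5 Hz mains notch so the fit band
#' is barely touched), empirical mode decomposition and band grouping
#' ([emd()], [band_combine()]), movement gating and theta-cycle detection
#' ([movement_mask()], [detect_cycles()]), then the pooled-PSD slope and
#' the per-cycle slopes over `band`. Frequencies inside the applied notch
#' stopbands (widened by 0.5 Hz for the filter shoulder) are interpolated
#' across for the estimators and excluded from the slope fits; the
#' per-cycle path additionally interpolates across `theta_repair_hz`
#' because a single-cycle window cannot reject the theta oscillation.
#'
#' @param rec a raw [recording()] (with a velocity trace for movement
#'   gating; without one the whole record is treated as moving).
#' @param target_fs analysis sampling rate, Hz.
#' @param band slope fit band, Hz.
#' @param params a [cycle_params()] object.
#' @param base_hz mains frequency passed to [notch_filter()].
#' @param notch_bw_hz half-width of each notch stopband.
#' @param theta_repair_hz theta region interpolated across for the
#'   per-cycle periodograms.
#' @return list with `rec` (conditioned recording), `bands`, `cycles`
#'   (slopes filled), `pooled_psd`, `pooled_fit`, and `slopes`
#'   (the per-cycle slope vector).
#' @export
theta_slope_pipeline <- function(rec, target_fs = 1000, band = c(30, 50),
                                 params = cycle_params(), base_hz = 50,
                                 notch_bw_hz = 0.5,
                                 theta_repair_hz = c(4, 13.5)) {
  pp <- preprocess(rec, target_fs = target_fs, base_hz = base_hz,
                   bw_hz = notch_bw_hz)
  dec <- emd(pp$lfp, fs_hz = pp$fs_hz)
  bands <- band_combine(dec)
  mask <- if (is.null(pp$velocity)) NULL else {
    movement_mask(pp$velocity, pp$fs_vel_hz, length(pp$lfp), pp$fs_hz,
                  thresh = params$velocity_thresh,
                  min_epoch_s = params$min_epoch_s)
  }
  cycles <- detect_cycles(bands, mask, params)
  # exclude the notch stopbands (widened by 0.5 Hz for the filter
  # shoulder) from the fits, and interpolate across them for the
  # estimators
  nb <- pp$meta$notch_bands_hz
  excl <- if (is.null(nb)) NULL else cbind(nb[, 1] - 0.5, nb[, 2] + 0.5)
  pooled_psd <- NULL
  pooled_fit <- NULL
  if (nrow(cycles) > 0L) {
    pooled_psd <- pooled_theta_psd(pp, cycles, repair_hz = excl)
    pooled_fit <- fit_slope(pooled_psd, band = band, exclude_hz = excl)
    cycles <- cycle_slopes(pp, cycles, band = band, exclude_hz = excl,
                           repair_hz = rbind(theta_repair_hz, excl))
  }
  list(rec = pp, bands = bands, cycles = cycles, pooled_psd = pooled_psd,
       pooled_fit = pooled_fit, slopes = cycles$slope_30_50)
}
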