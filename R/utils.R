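#' @keywords internal
#' @useDynLib eislope, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

#' Evaluate an expression under a temporary RNG state
#'
#' All generators in the package are pure functions of their `seed`
#' argument: the global RNG stream of the caller is saved, the seed is set,
#' and the previous stream is restored on exit.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Analytic signal via the frequency domain
#'
#' Hilbert-transform construction: the negative-frequency half of the
#' spectrum is zeroed and positive frequencies doubled, so the magnitude is
#' the instantaneous amplitude envelope and the phase derivative the
#' instantaneous frequency.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @keywords internal
#' @noRd
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Amplitude envelope of a series (analytic-signal magnitude)
#' @param x numeric vector.
#' @return non-negative numeric vector.
#' @export
envelope <- function(x) {
  Mod(analytic_signal(x))
}

#' Exact zero-phase high-pass via the frequency domain
#'
#' Zeroes every Fourier bin strictly below `hp_hz`. Used by the spectral
#' estimators to discard below-band content, which cannot inform an
#' in-band slope fit but leaks through short analysis windows and splice
#' points. `hp_hz = 0` is the identity.
#'
#' @param x numeric series.
#' @param fs sampling rate, Hz.
#' @param hp_hz cutoff; content below this frequency is removed exactly.
#' @return filtered series of the same length.
#' @export
spectral_highpass <- function(x, fs, hp_hz) {
  if (hp_hz <= 0) return(x)
  n <- length(x)
  X <- stats::fft(x)
  k <- floor(hp_hz * n / fs)
  if (k >= 1) {
    X[1:(k + 1)] <- 0
    X[(n - k + 1):n] <- 0
  } else {
    X[1] <- 0
  }
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Spectrum interpolation across notched frequency bands
#'
#' Rescales the Fourier amplitudes inside each given band to a log-linear
#' interpolation between the mean amplitudes of 1 Hz flanking strips,
#' keeping the phases. A notch filter leaves a spectral hole; when a PSD
#' is later estimated with windows much shorter than the notch width is
#' narrow (single theta cycles), the window kernel smears that hole
#' across neighbouring frequencies and biases slope fits. Interpolating
#' the hole restores a smooth background; the repaired bins themselves
#' should still be excluded from any fit (`exclude_hz` of
#' [fit_slope()]).
#'
#' @param x numeric series (after notch filtering).
#' @param fs sampling rate, Hz.
#' @param bands_hz two-column matrix of frequency bands to repair.
#' @param flank_hz width of the flanking strips used for interpolation.
#' @return the repaired series.
#' @export
spectral_repair <- function(x, fs, bands_hz, flank_hz = 1) {
  if (is.null(bands_hz)) return(x)
  bands_hz <- matrix(as.numeric(bands_hz), ncol = 2)
  n <- length(x)
  X <- stats::fft(x)
  f <- (0:(n - 1)) * fs / n
  half <- f <= fs / 2
  for (i in seq_len(nrow(bands_hz))) {
    lo <- bands_hz[i, 1]; hi <- bands_hz[i, 2]
    sel <- which(f >= lo & f <= hi & half)
    left <- which(f >= lo - flank_hz & f < lo & half)
    right <- which(f > hi & f <= hi + flank_hz & half)
    if (!length(sel) || !length(left) || !length(right)) next
    la <- mean(log(pmax(Mod(X[left]), 1e-300)))
    ra <- mean(log(pmax(Mod(X[right]), 1e-300)))
    fl <- mean(f[left]); fr <- mean(f[right])
    tgt <- exp(la + (ra - la) * (f[sel] - fl) / (fr - fl))
    amp <- Mod(X[sel])
    ph <- ifelse(amp > 0, X[sel] / amp, 1 + 0i)
    X[sel] <- tgt * ph
    mir <- n + 2L - sel
    mir_ok <- mir >= 1 & mir <= n & mir != sel
    X[mir[mir_ok]] <- Conj(X[sel][mir_ok])
  }
  Re(stats::fft(X, inverse = TRUE)) / n
}

# indices of local maxima / minima by 3-point comparison; on a plateau the
# first sample wins (a zero slope inherits the next nonzero slope, so the
# sign change is placed at the plateau's first sample)
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(max = integer(0), min = integer(0)))
  s <- sign(diff(x))
  z <- s == 0
  if (!any(z)) {
    # no plateaus: plain 3-point comparison
    d2 <- diff(s)
    return(list(max = which(d2 < 0) + 1L, min = which(d2 > 0) + 1L))
  }
  if (all(z)) return(list(max = integer(0), min = integer(0)))
  pos <- seq_along(s)
  v <- ifelse(s != 0, pos, Inf)
  nxt <- rev(cummin(rev(v)))          # nearest nonzero slope at/after i
  filled <- ifelse(is.finite(nxt), s[pmin(nxt, length(s))], 0)
  # trailing plateau: carry the last nonzero slope so no spurious boundary
  # extremum appears
  tail0 <- filled == 0
  if (any(tail0)) filled[tail0] <- s[max(which(s != 0))]
  d2 <- diff(filled)
  list(max = which(d2 < 0) + 1L, min = which(d2 > 0) + 1L)
}
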