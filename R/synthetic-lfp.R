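#' Colored (1/f^beta) noise by spectral synthesis
#'
#' Constructs a Gaussian-like noise series whose expected power spectrum is
#' proportional to `f^-beta` above a low-frequency knee, by direct
#' frequency-domain synthesis: Fourier amplitudes proportional to
#' `f^(-beta/2)`, independent uniform phases, Hermitian symmetry, inverse
#' FFT. The exponent is therefore analytic ground truth for any
#' spectral-slope estimator run downstream. The series is normalized to
#' zero mean and unit variance.
#'
#' Below `knee_hz` the spectrum is flat (at the knee value), mimicking the
#' low-frequency plateau of real field-potential aperiodic spectra. A pure
#' power law extended to the lowest resolvable frequency concentrates
#' almost all variance there, and window-sidelobe leakage from that mass
#' measurably flattens any tapered PSD estimate of the 30-50 Hz band; the
#' knee keeps the band's ground-truth exponent intact while emulating a
#' realistic spectrum. Set `knee_hz = 0` for the pure power law.
#'
#' @param beta spectral exponent (>= 0; 0 gives white noise).
#' @param n number of samples (>= 16).
#' @param fs sampling rate in Hz (sets the frequency grid only).
#' @param seed integer seed; the same seed yields a bit-identical series.
#' @param knee_hz low-frequency knee (default 1 Hz).
#' @return numeric vector of length `n`.
#' @examples
#' x <- generate_colored_noise(beta = 2, n = 4096, fs = 1000, seed = 1)
#' @export
generate_colored_noise <- function(beta, n, fs = 1000, seed = 1L,
                                   knee_hz = 1) {
  if (n < 16L) stop("n must be at least 16")
  if (beta < 0) stop("beta must be non-negative")
  with_seed(seed, {
    nfreq <- floor(n / 2)
    f <- (1:nfreq) * fs / n
    amp <- pmax(f, knee_hz)^(-beta / 2)
    phase <- stats::runif(nfreq, 0, 2 * pi)
    pos <- amp * exp(1i * phase)
    if (n %% 2 == 0) {
      # Nyquist bin must be real for a real series
      pos[nfreq] <- amp[nfreq] * sample(c(-1, 1), 1L)
      spec <- c(0, pos[-nfreq], pos[nfreq], Conj(rev(pos[-nfreq])))
    } else {
      spec <- c(0, pos, Conj(rev(pos)))
    }
    x <- Re(stats::fft(spec, inverse = TRUE)) / n
    x <- x - mean(x)
    x / stats::sd(x)
  })
}

#' Simulation parameters for a synthetic CA1 recording
#'
#' Bundles the ground-truth parameters of [generate_lfp()]. Defaults
#' describe an awake exploring mouse: a 1/f background with exponent
#' `beta`, a strong movement-gated theta oscillation that is frequency
#' modulated across 6-10 Hz, weaker 30-50 Hz gamma bursts amplitude-locked
#' to the theta peak (so the slope band contains oscillatory contamination,
#' as in real CA1), and 50 Hz mains contamination with one harmonic.
#' Amplitudes are in units of the background-noise standard deviation.
#'
#' @param duration_s recording length, seconds.
#' @param fs_hz sampling rate, Hz.
#' @param beta spectral exponent of the background noise.
#' @param noise_amp amplitude of the background noise (1 = the reference
#'   noise-SD unit the other amplitudes are expressed in; small values
#'   give a nearly noise-free oscillation for detector fixtures).
#' @param theta_freq_hz scalar for a fixed theta frequency, or a
#'   length-2 range for slow frequency modulation within it.
#' @param theta_amp theta amplitude (noise-SD units).
#' @param gamma_band_hz two-element band of the coupled gamma bursts.
#' @param gamma_amp peak burst amplitude relative to the background
#'   noise RMS within `gamma_band_hz` (1 = bursts at the local
#'   background level at the theta peak). A relative amplitude keeps the
#'   in-band contamination comparable across spectral exponents: an
#'   absolute amplitude would vanish against a shallow background and
#'   swamp a steep one.
#' @param line_hz mains frequency.
#' @param line_amp mains amplitude.
#' @param move_bouts `NULL` for continuous locomotion, otherwise a
#'   two-column matrix of movement epochs (start_s, end_s).
#' @param fs_vel_hz sampling rate of the generated velocity trace.
#' @param seed integer seed.
#' @return a list of class `lfp_sim_params`.
#' @export
lfp_sim_params <- function(duration_s = 120, fs_hz = 1000, beta = 2.5,
                           noise_amp = 1,
                           theta_freq_hz = c(6, 10), theta_amp = 3,
                           gamma_band_hz = c(30, 50), gamma_amp = 0.5,
                           line_hz = 50, line_amp = 0.5,
                           move_bouts = NULL, fs_vel_hz = 50, seed = 1L) {
  stopifnot(duration_s > 0, fs_hz > 0, beta >= 0)
  maxf <- max(theta_freq_hz, gamma_band_hz, 2 * line_hz)
  if (fs_hz < 2 * maxf) stop("fs_hz must be at least twice the highest generated frequency")
  p <- list(duration_s = duration_s, fs_hz = fs_hz, beta = beta,
            noise_amp = noise_amp,
            theta_freq_hz = theta_freq_hz, theta_amp = theta_amp,
            gamma_band_hz = gamma_band_hz, gamma_amp = gamma_amp,
            line_hz = line_hz, line_amp = line_amp,
            move_bouts = move_bouts, fs_vel_hz = fs_vel_hz,
            seed = as.integer(seed))
  class(p) <- "lfp_sim_params"
  p
}

#' Generate a synthetic CA1 LFP recording with embedded ground truth
#'
#' Builds `colored noise + movement-gated theta + theta-phase-coupled gamma
#' bursts + mains line (and one harmonic)`, together with a velocity trace
#' that exceeds 2 cm/s exactly during the movement epochs, and a ground
#' truth record for downstream validation.
#'
#' @param params an [lfp_sim_params()] object.
#' @return list with elements `rec` (a [recording()]) and `truth` (list
#'   with `true_beta`, `theta_epochs` (matrix start_s/end_s),
#'   `cycle_times` (theta-peak times, s), `moving_mask` (logical, at the
#'   velocity rate)).
#' @examples
#' sim <- generate_lfp(lfp_sim_params(duration_s = 20, seed = 7))
#' sim$rec
#' @export
generate_lfp <- function(params) {
  stopifnot(inherits(params, "lfp_sim_params"))
  p <- params
  fr <- range(p$theta_freq_hz)
  if (p$theta_amp > 0 && (fr[1] < 5 || fr[2] > 12)) {
    warning("theta frequency outside the 5-12 Hz band; generating anyway")
  }
  n <- round(p$duration_s * p$fs_hz)
  tt <- (seq_len(n) - 1) / p$fs_hz
  epochs <- if (is.null(p$move_bouts)) {
    matrix(c(0, p$duration_s), ncol = 2)
  } else {
    m <- matrix(as.numeric(p$move_bouts), ncol = 2)
    m[order(m[, 1]), , drop = FALSE]
  }
  colnames(epochs) <- c("start_s", "end_s")

  noise <- p$noise_amp * generate_colored_noise(p$beta, n, p$fs_hz,
                                                seed = p$seed)

  with_seed(p$seed + 1L, {
    # instantaneous theta frequency: slow random FM inside the stated range
    if (length(p$theta_freq_hz) == 1L) {
      f_inst <- rep(p$theta_freq_hz, n)
    } else {
      slow <- stats::filter(stats::rnorm(n), rep(1 / p$fs_hz, p$fs_hz),
                            sides = 2, circular = TRUE)
      slow <- as.numeric(slow) / max(stats::sd(slow), .Machine$double.eps)
      mid <- mean(fr); half <- diff(fr) / 2
      f_inst <- mid + half * tanh(slow)
    }
    # start theta at an upward zero-crossing: a record that opens exactly
    # on an extremum is a degenerate boundary case for envelope-based
    # analyses, which no real recording presents
    phase <- 2 * pi * cumsum(f_inst) / p$fs_hz
    phase <- phase - phase[1] - pi / 2

    gate <- numeric(n)
    for (i in seq_len(nrow(epochs))) {
      i0 <- max(1L, floor(epochs[i, 1] * p$fs_hz) + 1L)
      i1 <- min(n, ceiling(epochs[i, 2] * p$fs_hz))
      gate[i0:i1] <- 1
    }
    theta <- p$theta_amp * cos(phase) * gate
    # broadband gamma: narrowband noise carrier amplitude-locked to the
    # theta peak (real CA1 gamma is stochastic, not a coherent tone),
    # scaled relative to the background level inside the gamma band
    gamma <- numeric(n)
    if (p$gamma_amp > 0) {
      carrier <- signal::filtfilt(
        signal::butter(3, p$gamma_band_hz / (p$fs_hz / 2), type = "pass"),
        stats::rnorm(n))
      carrier <- carrier / stats::sd(carrier)
      Xn <- stats::fft(noise)
      fgrid <- (0:(n - 1)) * p$fs_hz / n
      inband <- fgrid >= p$gamma_band_hz[1] & fgrid <= p$gamma_band_hz[2]
      band_rms <- sqrt(2 * sum(Mod(Xn[inband])^2) / n^2)
      gamma <- p$gamma_amp * band_rms * (1 + cos(phase)) / 2 * carrier * gate
    }
    line <- p$line_amp * (sin(2 * pi * p$line_hz * tt) +
                            0.3 * sin(2 * pi * 2 * p$line_hz * tt))
    lfp <- noise + theta + gamma + line

    # theta peaks: upward crossings of phase through multiples of 2*pi,
    # strictly inside the record and inside a movement epoch
    kmax <- floor(phase[n] / (2 * pi))
    cycle_times <- numeric(0)
    if (p$theta_amp > 0 && kmax >= 1) {
      targets <- 2 * pi * seq_len(kmax)
      cycle_times <- stats::approx(phase, tt, xout = targets, ties = "ordered")$y
      cycle_times <- cycle_times[!is.na(cycle_times) &
                                   cycle_times > 0 & cycle_times < p$duration_s]
      in_epoch <- vapply(cycle_times, function(ct) {
        any(ct >= epochs[, 1] & ct <= epochs[, 2])
      }, logical(1))
      cycle_times <- cycle_times[in_epoch]
    }

    # velocity at its own (lower) rate: > 2 cm/s exactly while moving
    nv <- round(p$duration_s * p$fs_vel_hz)
    tv <- (seq_len(nv) - 1) / p$fs_vel_hz
    moving <- vapply(tv, function(ct) {
      any(ct >= epochs[, 1] & ct < epochs[, 2])
    }, logical(1))
    vel <- stats::runif(nv, 0, 1.5)
    if (any(moving)) {
      run <- 8 + 3 * as.numeric(stats::filter(stats::rnorm(nv), rep(0.2, 5),
                                              sides = 2, circular = TRUE))
      vel[moving] <- pmax(run[moving], 2.5)
    }

    rec <- recording(lfp, p$fs_hz, velocity = vel, fs_vel_hz = p$fs_vel_hz,
                     meta = list(synthetic = TRUE, beta = p$beta,
                                 seed = p$seed))
    truth <- list(true_beta = p$beta,
                  theta_epochs = if (p$theta_amp > 0) epochs else
                    matrix(numeric(0), ncol = 2,
                           dimnames = list(NULL, c("start_s", "end_s"))),
                  cycle_times = cycle_times,
                  moving_mask = moving)
    list(rec = rec, truth = truth)
  })
}
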