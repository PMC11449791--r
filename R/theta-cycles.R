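#' Parameters for theta-cycle detection
#'
#' @param velocity_thresh locomotion threshold in cm/s; samples are
#'   "moving" when velocity is strictly greater.
#' @param min_valley_sep_ms minimum separation of a cycle's flanking
#'   valleys (71 ms, ~14 Hz).
#' @param max_valley_sep_ms maximum valley separation (200 ms, ~5 Hz).
#' @param min_epoch_s movement epochs shorter than this are discarded.
#' @return a list of class `cycle_params`.
#' @export
cycle_params <- function(velocity_thresh = 2, min_valley_sep_ms = 71,
                         max_valley_sep_ms = 200, min_epoch_s = 0.5) {
  stopifnot(min_valley_sep_ms > 0,
            min_valley_sep_ms < max_valley_sep_ms)
  structure(list(velocity_thresh = velocity_thresh,
                 min_valley_sep_ms = min_valley_sep_ms,
                 max_valley_sep_ms = max_valley_sep_ms,
                 min_epoch_s = min_epoch_s),
            class = "cycle_params")
}

#' Movement mask from a velocity trace
#'
#' Marks periods of active exploration: velocity strictly greater than
#' `thresh` cm/s. Epochs shorter than `min_epoch_s` are dropped, and the
#' mask is transferred to the LFP time base.
#'
#' @param velocity numeric velocity trace (cm/s).
#' @param fs_vel sampling rate of the velocity trace (Hz).
#' @param n_lfp number of LFP samples the mask must cover.
#' @param fs_lfp LFP sampling rate (Hz).
#' @param thresh threshold in cm/s (strict `>`).
#' @param min_epoch_s minimum epoch duration in seconds.
#' @return logical vector of length `n_lfp`.
#' @export
movement_mask <- function(velocity, fs_vel, n_lfp, fs_lfp, thresh = 2,
                          min_epoch_s = 0.5) {
  stopifnot(all(is.finite(velocity)))
  moving <- velocity > thresh
  if (!any(moving)) return(rep(FALSE, n_lfp))
  r <- rle(moving)
  keep <- r$values & (r$lengths / fs_vel >= min_epoch_s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mask <- rep(FALSE, n_lfp)
  for (i in which(keep)) {
    t0 <- (starts[i] - 1L) / fs_vel
    t1 <- ends[i] / fs_vel
    i0 <- max(1L, floor(t0 * fs_lfp) + 1L)
    i1 <- min(n_lfp, ceiling(t1 * fs_lfp))
    if (i0 <= i1) mask[i0:i1] <- TRUE
  }
  mask
}

#' Detect individual theta cycles
#'
#' A candidate theta cycle is a local maximum of the theta-band signal
#' flanked by a pair of consecutive local minima, where peak and valleys
#' all have absolute value above the amplitude envelope of the low-band
#' (<5 Hz) signal at their sample, the valley separation lies within
#' `[min_valley_sep_ms, max_valley_sep_ms]`, and the whole valley-to-valley
#' stretch lies inside a movement epoch. "Consecutive" means no other
#' qualifying valley lies between the pair and exactly one qualifying peak
#' does. When candidates overlap, cycles are accepted greedily left to
#' right.
#'
#' @param bands a `band_signals` object from [band_combine()].
#' @param mask logical movement mask on the same time base, or `NULL` to
#'   treat the whole record as moving.
#' @param params a [cycle_params()] object.
#' @return a data.frame of class `theta_cycles` with columns `peak_idx`,
#'   `valley_left_idx`, `valley_right_idx`, `peak_s`, `valley_left_s`,
#'   `valley_right_s`, `duration_ms`, `slope_30_50` (NA until filled by
#'   [cycle_slopes()]). Zero rows when nothing qualifies.
#' @export
detect_cycles <- function(bands, mask = NULL, params = cycle_params()) {
  stopifnot(inherits(bands, "band_signals"))
  fs <- bands$fs_hz
  theta <- bands$theta
  n <- length(theta)
  if (is.null(mask)) mask <- rep(TRUE, n)
  stopifnot(length(mask) == n)
  empty <- data.frame(peak_idx = integer(0), valley_left_idx = integer(0),
                      valley_right_idx = integer(0), peak_s = numeric(0),
                      valley_left_s = numeric(0), valley_right_s = numeric(0),
                      duration_ms = numeric(0), slope_30_50 = numeric(0))
  class(empty) <- c("theta_cycles", "data.frame")
  if (!any(mask) || stats::sd(theta) == 0) return(empty)

  env_low <- envelope(bands$low)
  ext <- local_extrema(theta)
  peaks <- ext$max[theta[ext$max] > env_low[ext$max] & mask[ext$max]]
  valleys <- ext$min[-theta[ext$min] > env_low[ext$min] & mask[ext$min]]
  if (length(peaks) == 0L || length(valleys) < 2L) return(empty)

  min_sep <- params$min_valley_sep_ms / 1000 * fs
  max_sep <- params$max_valley_sep_ms / 1000 * fs
  rows <- vector("list", length(peaks))
  last_vr <- -Inf
  nacc <- 0L
  for (pk in peaks) {
    il <- findInterval(pk - 1L, valleys)          # last valley strictly before
    if (il < 1L || il >= length(valleys)) next
    vl <- valleys[il]
    vr <- valleys[il + 1L]
    if (vr <= pk) next                            # peak not between the pair
    # exactly one qualifying peak between the consecutive valleys
    if (sum(peaks > vl & peaks < vr) != 1L) next
    sep <- vr - vl
    if (sep < min_sep || sep > max_sep) next
    if (!all(mask[vl:vr])) next
    if (vl < last_vr) next                        # greedy non-overlap
    nacc <- nacc + 1L
    last_vr <- vr
    rows[[nacc]] <- c(pk, vl, vr)
  }
  if (nacc == 0L) return(empty)
  m <- do.call(rbind, rows[seq_len(nacc)])
  out <- data.frame(
    peak_idx = m[, 1], valley_left_idx = m[, 2], valley_right_idx = m[, 3],
    peak_s = (m[, 1] - 1) / fs, valley_left_s = (m[, 2] - 1) / fs,
    valley_right_s = (m[, 3] - 1) / fs,
    duration_ms = (m[, 3] - m[, 2]) / fs * 1000,
    slope_30_50 = NA_real_
  )
  class(out) <- c("theta_cycles", "data.frame")
  out
}
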