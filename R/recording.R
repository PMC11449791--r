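#' Construct a Recording object
#'
#' A `recording` bundles a continuous LFP trace with its sampling rate, an
#' aligned velocity trace (possibly at a lower rate) and free-form metadata
#' (subject, group, stage).
#'
#' @param lfp numeric vector, the LFP samples (finite).
#' @param fs_hz LFP sampling rate, samples/s.
#' @param velocity numeric vector of running speed in cm/s, or `NULL`.
#' @param fs_vel_hz sampling rate of the velocity trace.
#' @param meta named list of metadata tags.
#' @return object of class `recording`.
#' @export
recording <- function(lfp, fs_hz, velocity = NULL, fs_vel_hz = NULL,
                      meta = list()) {
  stopifnot(is.numeric(lfp), length(lfp) > 0, fs_hz > 0)
  if (!all(is.finite(lfp))) stop("LFP samples must be finite")
  if (!is.null(velocity) && is.null(fs_vel_hz)) {
    stop("`fs_vel_hz` is required when a velocity trace is supplied")
  }
  structure(
    list(lfp = as.numeric(lfp), fs_hz = fs_hz,
         velocity = if (is.null(velocity)) NULL else as.numeric(velocity),
         fs_vel_hz = fs_vel_hz, meta = meta),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  dur <- length(x$lfp) / x$fs_hz
  cat(sprintf("<recording> %.1f s at %g Hz (%d samples)\n",
              dur, x$fs_hz, length(x$lfp)))
  if (!is.null(x$velocity)) {
    cat(sprintf("  velocity: %d samples at %g Hz\n",
                length(x$velocity), x$fs_vel_hz))
  }
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.recording <- function(x) length(x$lfp)

#' Write / read a recording as CSV
#'
#' Plain-text interchange format: columns `time`, `lfp` and (when present)
#' `velocity` interpolated onto the LFP time base. The sampling rates are
#' stored in a `# fs_lfp_hz=... fs_vel_hz=...` header comment.
#'
#' @param rec a `recording`.
#' @param path file path.
#' @return `write_recording_csv` returns `path` invisibly;
#'   `read_recording_csv` returns a `recording`.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  n <- length(rec$lfp)
  tt <- (seq_len(n) - 1) / rec$fs_hz
  df <- data.frame(time = tt, lfp = rec$lfp)
  hdr <- sprintf("# fs_lfp_hz=%g", rec$fs_hz)
  if (!is.null(rec$velocity)) {
    tv <- (seq_along(rec$velocity) - 1) / rec$fs_vel_hz
    df$velocity <- stats::approx(tv, rec$velocity, xout = tt, rule = 2)$y
    hdr <- paste0(hdr, sprintf(" fs_vel_hz=%g", rec$fs_hz))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  fs <- as.numeric(sub(".*fs_lfp_hz=([0-9.eE+-]+).*", "\\1", hdr))
  fs_vel <- if (grepl("fs_vel_hz=", hdr)) {
    as.numeric(sub(".*fs_vel_hz=([0-9.eE+-]+).*", "\\1", hdr))
  } else NULL
  df <- utils::read.csv(path, comment.char = "#")
  recording(df$lfp, fs,
            velocity = if ("velocity" %in% names(df)) df$velocity else NULL,
            fs_vel_hz = fs_vel)
}
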