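#' Muscle channel labels
#'
#' The ten surface-EMG channels used throughout the package: vastus lateralis
#' (VL), vastus medialis (VM), biceps femoris (BF), semitendinosus (SM) and
#' gastrocnemius medial head (GM) of the right (R) and left (L) legs.
#'
#' @export
MUSCLE_CHANNELS <- c("RVL", "RVM", "RBF", "RSM", "RGM",
                     "LVL", "LVM", "LBF", "LSM", "LGM")

# muscles that enter stride-cycle (time-domain) analysis; SM and GM are
# excluded from timing features but keep their frequency features
STRIDE_MUSCLES <- c("RBF", "RVM", "RVL", "LBF", "LVM", "LVL")

#' Construct a multichannel sEMG recording
#'
#' @param samples numeric matrix (rows = time samples) or named list of equal
#'   length numeric vectors, amplitudes in microvolts.
#' @param fs sampling rate in Hz (default 1926, the Delsys Trigno rate).
#' @param channel_ids character vector of channel labels, a subset of
#'   [MUSCLE_CHANNELS]. Taken from column names when `samples` is a matrix.
#' @return An object of class `semg_recording` with elements `samples`
#'   (matrix, one column per channel), `channel_ids`, `fs`, and `f_nyq = fs/2`.
#' @export
recording <- function(samples, fs = 1926, channel_ids = NULL) {
  if (is.list(samples) && !is.data.frame(samples)) {
    if (is.null(channel_ids)) channel_ids <- names(samples)
    len <- unique(lengths(samples))
    if (length(len) != 1L)
      stop_with("format_error", "all channels must have the same length")
    samples <- do.call(cbind, lapply(samples, as.numeric))
  } else {
    samples <- as.matrix(samples)
    if (is.null(channel_ids)) channel_ids <- colnames(samples)
  }
  assert_scalar_num(fs, "fs")
  if (fs <= 0) stop_with("config_error", "fs must be > 0 (got %g)", fs)
  if (is.null(channel_ids))
    stop_with("format_error", "channel labels are required")
  channel_ids <- as.character(channel_ids)
  if (anyDuplicated(channel_ids))
    stop_with("format_error", "duplicate channel label: %s",
              channel_ids[duplicated(channel_ids)][1])
  unknown <- setdiff(channel_ids, MUSCLE_CHANNELS)
  if (length(unknown))
    stop_with("format_error", "unknown channel label(s): %s",
              paste(unknown, collapse = ", "))
  if (length(channel_ids) != ncol(samples))
    stop_with("format_error", "channel label count does not match data columns")
  colnames(samples) <- channel_ids
  structure(list(samples = samples, channel_ids = channel_ids,
                 fs = fs, f_nyq = fs / 2),
            class = "semg_recording")
}

#' @export
print.semg_recording <- function(x, ...) {
  cat(sprintf("<semg_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$samples), nrow(x$samples), x$fs, nrow(x$samples) / x$fs))
  cat("  channels:", paste(x$channel_ids, collapse = " "), "\n")
  invisible(x)
}

#' Read a multichannel sEMG recording from CSV
#'
#' Expects a comma-separated file with one header row naming the channels
#' (labels from [MUSCLE_CHANNELS]) and a numeric body, one row per sample.
#'
#' @param path file path.
#' @param fs sampling rate in Hz.
#' @return A [recording()].
#' @export
read_recording <- function(path, fs = 1926) {
  if (fs <= 0) stop_with("config_error", "fs must be > 0 (got %g)", fs)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (nrow(raw) == 0L) stop_with("format_error", "empty recording file: %s", path)
  mat <- matrix(NA_real_, nrow(raw), ncol(raw))
  for (j in seq_len(ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) & !is.na(raw[[j]]))
    if (length(bad))
      stop_with("parse_error", "non-numeric value in column '%s' at data row %d",
                names(raw)[j], bad[1])
    mat[, j] <- v
  }
  colnames(mat) <- names(raw)
  recording(mat, fs = fs)
}

#' Write a recording to CSV
#'
#' @param rec a [recording()].
#' @param path output file path.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "semg_recording"))
  utils::write.csv(as.data.frame(rec$samples), path, row.names = FALSE)
  invisible(path)
}

#' Construct a sparse blood-lactate series
#'
#' @param times sample times in seconds from test start, strictly increasing.
#' @param values blood lactate concentrations in mmol/L, non-negative.
#' @return An object of class `lactate_series` with `times`, `values` and
#'   `t_max` (the last sampling time).
#' @export
lactate_series <- function(times, values) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop_with("format_error", "times and values differ in length")
  if (length(times) < 2L)
    stop_with("insufficient_data", "need at least 2 lactate samples, got %d",
              length(times))
  ord <- order(times)
  times <- times[ord]; values <- values[ord]
  if (anyDuplicated(times))
    stop_with("validation_error", "duplicate lactate timestamp: %g s",
              times[duplicated(times)][1])
  if (times[1] < 0)
    stop_with("validation_error", "lactate times must be >= 0")
  if (any(values < 0))
    stop_with("validation_error", "negative lactate value: %g mmol/L",
              min(values))
  structure(list(times = times, values = values, t_max = times[length(times)]),
            class = "lactate_series")
}

#' Read a blood-lactate series from CSV
#'
#' Two-column comma-separated file `time_s, lactate_mmol_per_l`. Rows are
#' sorted by time; duplicate timestamps and negative concentrations are
#' rejected.
#'
#' @param path file path.
#' @return A [lactate_series()].
#' @export
read_lactate <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  if (ncol(raw) < 2L)
    stop_with("format_error", "lactate file needs 2 columns (time_s, mmol/L)")
  lactate_series(raw[[1]], raw[[2]])
}

#' Write a lactate series to CSV
#'
#' @param series a [lactate_series()].
#' @param path output file path.
#' @export
write_lactate <- function(series, path) {
  stopifnot(inherits(series, "lactate_series"))
  utils::write.csv(data.frame(time_s = series$times,
                              lactate_mmol_per_l = series$values),
                   path, row.names = FALSE)
  invisible(path)
}
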