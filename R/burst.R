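#' Linear envelope of an sEMG channel
#'
#' Full-wave rectification followed by zero-phase Butterworth low-pass
#' smoothing. The envelope tracks gross muscle activity and is the input to
#' burst detection.
#'
#' @param samples numeric vector, preprocessed sEMG.
#' @param fs sampling rate (Hz).
#' @param env_cutoff smoothing cutoff (Hz, default 5; well below running
#'   cadence harmonics but fast enough to follow 0.3 s bursts).
#' @param order smoothing filter order.
#' @return non-negative numeric vector, same length as input.
#' @export
envelope <- function(samples, fs, env_cutoff = 5, order = 4) {
  if (!length(samples)) stop_with("insufficient_data", "empty signal")
  if (env_cutoff >= fs / 2)
    stop_with("config_error", "envelope cutoff must be below Nyquist")
  sos <- butter_sos(order, env_cutoff, fs, "lowpass")
  pmax(sos_filtfilt(sos, abs(samples)), 0)
}

# local maxima of v (strict on the left, non-strict right, plateaus resolved
# to their first sample); returns indices
#' @noRd
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

# keep the strongest event of any run of same-type events closer than
# min_interval seconds
#' @noRd
merge_close_events <- function(idx, strength, fs, min_interval) {
  if (length(idx) <= 1L) return(idx)
  keep <- integer(0)
  cluster <- idx[1]; cstr <- strength[1]
  for (j in 2:length(idx)) {
    if ((idx[j] - cluster[length(cluster)]) / fs < min_interval) {
      cluster <- c(cluster, idx[j]); cstr <- c(cstr, strength[j])
    } else {
      keep <- c(keep, cluster[which.max(cstr)])
      cluster <- idx[j]; cstr <- strength[j]
    }
  }
  c(keep, cluster[which.max(cstr)])
}

#' Detect muscle-activity bursts in one channel
#'
#' Activation moments A(i) are the local maxima of the derivative of the
#' smoothed envelope (steepest rise); deactivation moments D(i) are the local
#' minima (steepest fall). Candidate extrema must reach
#' `prominence_fraction` of the largest absolute derivative; same-type events
#' closer than `min_interval` are merged (strongest kept) and the event
#' sequence is reduced to strict A, D, A, D... alternation by dropping the
#' weaker of two consecutive same-type events.
#'
#' @param samples preprocessed channel.
#' @param fs sampling rate (Hz).
#' @param env_cutoff envelope smoothing cutoff (Hz).
#' @param prominence_fraction threshold as a fraction of max |derivative|
#'   (default 0.2).
#' @param min_interval minimum spacing between same-type events (s,
#'   default 0.4; sized to running cadence 60-110 strides/min).
#' @return data.frame with columns `A` and `D` (seconds), one row per burst,
#'   time-ordered and non-overlapping. A flat signal yields zero rows.
#' @export
detect_bursts <- function(samples, fs, env_cutoff = 5,
                          prominence_fraction = 0.2, min_interval = 0.4) {
  env <- envelope(samples, fs, env_cutoff)
  n <- length(env)
  empty <- data.frame(A = numeric(0), D = numeric(0))
  if (n < 5L) return(empty)
  d <- c(0, (env[3:n] - env[1:(n - 2)]) * fs / 2, 0)  # centered derivative
  dmax <- max(abs(d))
  # flat signal: envelope changes by less than 1e-6 of its scale per second
  if (dmax <= 1e-6 * max(env)) return(empty)
  thr <- prominence_fraction * dmax
  iA <- local_maxima(d);  iA <- iA[d[iA] >= thr]
  iD <- local_maxima(-d); iD <- iD[-d[iD] >= thr]
  iA <- merge_close_events(iA, d[iA], fs, min_interval)
  iD <- merge_close_events(iD, -d[iD], fs, min_interval)
  if (!length(iA) || !length(iD)) return(empty)
  ev <- rbind(data.frame(i = iA, type = "A", s = d[iA]),
              data.frame(i = iD, type = "D", s = -d[iD]))
  ev <- ev[order(ev$i), ]
  # enforce alternation starting with A: among consecutive same-type events
  # keep the stronger
  out <- ev[0, ]
  for (r in seq_len(nrow(ev))) {
    if (!nrow(out)) {
      if (ev$type[r] == "A") out <- ev[r, ]
    } else if (ev$type[r] == out$type[nrow(out)]) {
      if (ev$s[r] > out$s[nrow(out)]) out[nrow(out), ] <- ev[r, ]
    } else {
      out <- rbind(out, ev[r, ])
    }
  }
  if (nrow(out) && out$type[nrow(out)] == "A") out <- out[-nrow(out), ]
  if (!nrow(out)) return(empty)
  a <- out$i[out$type == "A"]; dd <- out$i[out$type == "D"]
  data.frame(A = (a - 1) / fs, D = (dd - 1) / fs)
}

#' Detect bursts on every channel of a recording
#'
#' @param rec a preprocessed [recording()].
#' @param env_cutoff,prominence_fraction,min_interval see [detect_bursts()].
#' @return named list of per-channel burst data.frames.
#' @export
detect_bursts_all <- function(rec, env_cutoff = 5, prominence_fraction = 0.2,
                              min_interval = 0.4) {
  stopifnot(inherits(rec, "semg_recording"))
  out <- lapply(rec$channel_ids, function(ch)
    detect_bursts(rec$samples[, ch], rec$fs, env_cutoff,
                  prominence_fraction, min_interval))
  names(out) <- rec$channel_ids
  out
}

#' Assemble stride cycles from per-channel bursts
#'
#' A stride cycle spans consecutive activations of the right biceps femoris
#' (RBF), the first muscle to fire in each stride. For each of the six
#' stride muscles (RBF, RVM, RVL, LBF, LVM, LVL) the burst whose activation
#' falls inside `[start, end)` is attached; when several qualify the earliest
#' is used. Cycles missing any required muscle are flagged incomplete (kept,
#' but excluded from time-feature aggregation). SM and GM channels never
#' enter stride assembly.
#'
#' @param bursts_by_channel named list of burst data.frames as returned by
#'   [detect_bursts_all()].
#' @return data.frame with one row per cycle: `start`, `end`, `duration`,
#'   `complete`, and `A_<muscle>` / `D_<muscle>` columns for the six stride
#'   muscles (NA when absent).
#' @export
build_stride_cycles <- function(bursts_by_channel) {
  rbf <- bursts_by_channel[["RBF"]]
  if (is.null(rbf) || nrow(rbf) < 2L)
    stop_with("no_strides", "no stride cycles detected")
  starts <- rbf$A[-nrow(rbf)]
  ends <- rbf$A[-1]
  cyc <- data.frame(start = starts, end = ends, duration = ends - starts)
  for (m in STRIDE_MUSCLES) {
    cyc[[paste0("A_", m)]] <- NA_real_
    cyc[[paste0("D_", m)]] <- NA_real_
    b <- bursts_by_channel[[m]]
    if (is.null(b) || !nrow(b)) next
    for (i in seq_len(nrow(cyc))) {
      hit <- which(b$A >= cyc$start[i] & b$A < cyc$end[i])
      if (length(hit)) {
        hit <- hit[1]  # earliest activation in the window
        cyc[[paste0("A_", m)]][i] <- b$A[hit]
        cyc[[paste0("D_", m)]][i] <- b$D[hit]
      }
    }
  }
  cyc$complete <- stats::complete.cases(
    cyc[, paste0("A_", STRIDE_MUSCLES), drop = FALSE])
  cyc
}
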