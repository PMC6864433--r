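# the nine activation-phase pairs, in reporting order
PHASE_PAIRS <- list(
  c("RBF", "RVM"), c("RBF", "RVL"), c("RVM", "RVL"),
  c("LBF", "LVM"), c("LBF", "LVL"), c("LVM", "LVL"),
  c("RBF", "LBF"), c("RVM", "LVM"), c("RVL", "LVL"))

#' Phase shift between two muscles in a stride cycle
#'
#' The activation-time difference of muscles Y and X expressed as a fraction
#' of the stride duration: `(A_Y - A_X) / (A_RBF(i+1) - A_RBF(i))`.
#'
#' @param cycle one row of [build_stride_cycles()] output.
#' @param X,Y muscle labels among the six stride muscles.
#' @return dimensionless fraction (0 when X == Y, negative when Y fires
#'   before X).
#' @export
phase_shift <- function(cycle, X, Y) {
  aX <- cycle[[paste0("A_", X)]]; aY <- cycle[[paste0("A_", Y)]]
  if (is.na(aX) || is.na(aY))
    stop_with("incomplete_cycle", "muscle %s or %s missing from cycle", X, Y)
  (aY - aX) / cycle$duration
}

#' Active-time percentage of a muscle in a stride cycle
#'
#' Fraction of the stride during which the muscle is active:
#' `(D_X - A_X) / (A_RBF(i+1) - A_RBF(i))`.
#'
#' @inheritParams phase_shift
#' @return fraction in (0, 1] for bursts contained in the cycle.
#' @export
active_time_pct <- function(cycle, X) {
  aX <- cycle[[paste0("A_", X)]]; dX <- cycle[[paste0("D_", X)]]
  if (is.na(aX) || is.na(dX))
    stop_with("incomplete_cycle", "muscle %s missing from cycle", X)
  (dX - aX) / cycle$duration
}

#' RMS of a muscle's signal over its active interval
#'
#' Root-mean-square of S(t) over the samples in `[A_X, D_X]`.
#'
#' @param samples the muscle's preprocessed channel.
#' @param fs sampling rate (Hz).
#' @param A,D activation and deactivation times (s).
#' @return RMS amplitude (same units as the signal, microvolts).
#' @export
cycle_rms <- function(samples, fs, A, D) {
  i0 <- floor(A * fs) + 1L
  i1 <- min(floor(D * fs) + 1L, length(samples))
  if (is.na(A) || is.na(D) || i1 < i0)
    stop_with("incomplete_cycle", "empty active interval")
  sqrt(mean(samples[i0:i1]^2))
}

#' Per-stride timing and amplitude features
#'
#' For every complete stride cycle computes the nine phase shifts, the six
#' active-time percentages and the six cycle RMS values, stamped with the
#' cycle's starting RBF activation.
#'
#' @param cycles output of [build_stride_cycles()].
#' @param rec the preprocessed [recording()] (needed for RMS; must contain
#'   the six stride muscles).
#' @return data.frame, one row per complete cycle: `t_s`, `phi_<X>_<Y>`,
#'   `alpha_<X>`, `rho_<X>`.
#' @export
stride_feature_rows <- function(cycles, rec) {
  keep <- which(cycles$complete)
  cols <- c("t_s",
            vapply(PHASE_PAIRS, function(p) paste0("phi_", p[1], "_", p[2]), ""),
            paste0("alpha_", STRIDE_MUSCLES),
            paste0("rho_", STRIDE_MUSCLES))
  out <- matrix(NA_real_, length(keep), length(cols),
                dimnames = list(NULL, cols))
  for (r in seq_along(keep)) {
    cy <- cycles[keep[r], ]
    vals <- cy$start
    for (p in PHASE_PAIRS) vals <- c(vals, phase_shift(cy, p[1], p[2]))
    for (m in STRIDE_MUSCLES) vals <- c(vals, active_time_pct(cy, m))
    for (m in STRIDE_MUSCLES)
      vals <- c(vals, cycle_rms(rec$samples[, m], rec$fs,
                                cy[[paste0("A_", m)]], cy[[paste0("D_", m)]]))
    out[r, ] <- vals
  }
  as.data.frame(out)
}

#' Names of the 51 session-level time-domain features
#'
#' Features 1-18 are the mean (am) and standard deviation (sd) of the nine
#' phase-shift pairs, 19-30 of the six active-time percentages, 31-42 of the
#' six cycle RMS values; 43-51 are the right-left asymmetries of the
#' within-leg phase shifts, the active-time percentages and the RMS values.
#'
#' @return character vector of length 51.
#' @export
time_feature_names <- function() {
  phi <- vapply(PHASE_PAIRS, function(p) paste0("phi_", p[1], "_", p[2]), "")
  c(as.vector(rbind(paste0(phi, "_am"), paste0(phi, "_sd"))),
    as.vector(rbind(paste0("alpha_", STRIDE_MUSCLES, "_am"),
                    paste0("alpha_", STRIDE_MUSCLES, "_sd"))),
    as.vector(rbind(paste0("rho_", STRIDE_MUSCLES, "_am"),
                    paste0("rho_", STRIDE_MUSCLES, "_sd"))),
    c("asym_phi_BF_VM", "asym_phi_BF_VL", "asym_phi_VM_VL"),
    paste0("asym_alpha_", c("BF", "VM", "VL")),
    paste0("asym_rho_", c("BF", "VM", "VL")))
}

#' Indices of the time-event feature subset
#'
#' The 36 time-event features are the time-domain features with every
#' amplitude (RMS-derived) quantity removed: entries 1-30 and 43-48.
#'
#' @return integer vector of length 36.
#' @export
time_event_indices <- function() c(1:30, 43:48)

#' Aggregate per-stride rows into the 51-entry session vector
#'
#' Arithmetic mean and sample standard deviation (1/(n-1) divisor) of each
#' per-stride feature, plus the nine right-left asymmetries
#' `|mean_right - mean_left|` for the within-leg phase pairs (BF,VM / BF,VL /
#' VM,VL), the active-time percentages and the RMS values.
#'
#' @param rows output of [stride_feature_rows()] (n >= 2 strides).
#' @return named numeric vector of length 51 (see [time_feature_names()]).
#' @export
aggregate_session <- function(rows) {
  if (nrow(rows) < 2L)
    stop_with("insufficient_strides",
              "need >= 2 strides for SD, got %d", nrow(rows))
  base <- setdiff(names(rows), "t_s")
  am <- vapply(rows[base], mean, numeric(1))
  sd_ <- vapply(rows[base], stats::sd, numeric(1))
  asym <- c(
    abs(am[["phi_RBF_RVM"]] - am[["phi_LBF_LVM"]]),
    abs(am[["phi_RBF_RVL"]] - am[["phi_LBF_LVL"]]),
    abs(am[["phi_RVM_RVL"]] - am[["phi_LVM_LVL"]]),
    abs(am[["alpha_RBF"]] - am[["alpha_LBF"]]),
    abs(am[["alpha_RVM"]] - am[["alpha_LVM"]]),
    abs(am[["alpha_RVL"]] - am[["alpha_LVL"]]),
    abs(am[["rho_RBF"]] - am[["rho_LBF"]]),
    abs(am[["rho_RVM"]] - am[["rho_LVM"]]),
    abs(am[["rho_RVL"]] - am[["rho_LVL"]]))
  stats::setNames(c(as.vector(rbind(am, sd_)), asym), time_feature_names())
}

#' Sliding-window session vectors
#'
#' Computes the 51-entry aggregate over sliding stride windows so time-domain
#' features acquire a time axis and can be paired with lactate phase labels.
#' A window wider than the available strides degrades to one whole-session
#' vector.
#'
#' @param rows output of [stride_feature_rows()].
#' @param window window length in strides (default 20).
#' @param hop hop between windows in strides (default 5).
#' @return data.frame: `t_s` (window-center stride timestamp) plus 51
#'   feature columns.
#' @export
windowed_time_features <- function(rows, window = 20, hop = 5) {
  n <- nrow(rows)
  if (window > n) {
    v <- aggregate_session(rows)
    return(cbind(data.frame(t_s = rows$t_s[ceiling(n / 2)]),
                 as.data.frame(as.list(v))))
  }
  starts <- seq(1L, n - window + 1L, by = hop)
  out <- lapply(starts, function(s) {
    w <- rows[s:(s + window - 1L), ]
    cbind(data.frame(t_s = w$t_s[ceiling(window / 2)]),
          as.data.frame(as.list(aggregate_session(w))))
  })
  do.call(rbind, out)
}
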