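#' Specification for a synthetic running session
#'
#' Defines the ground-truth structure of one simulated incremental treadmill
#' session: stride timing, per-muscle activation offsets within the stride
#' (BF fires first, then VM, then VL; the left leg runs half a cycle out of
#' phase), burst shape, sEMG carrier band, the class-dependent spectral and
#' amplitude effects injected into the vastus lateralis channels, and the
#' three-phase piecewise-linear lactate profile with its breakpoints.
#'
#' @param duration session length (s).
#' @param fs sampling rate (Hz).
#' @param stride_period nominal stride duration (s).
#' @param stride_jitter fractional SD of per-stride period jitter.
#' @param offsets named activation offsets (fraction of cycle) per muscle
#'   group; left-leg channels add 0.5.
#' @param duty burst duty cycle (fraction of stride the muscle is active).
#' @param ramp rise/fall time of the cosine-tapered burst gate (s). The
#'   ground-truth activation A is the center of the rising ramp (where the
#'   envelope derivative peaks); D is the center of the falling ramp.
#' @param carrier_lo,carrier_hi sEMG carrier band (Hz).
#' @param class2_shift_hz upward carrier shift of the target channels during
#'   the anaerobic phase (Hz).
#' @param class2_amp_drift fractional amplitude increase during the
#'   anaerobic phase.
#' @param class3_shift_hz carrier shift during recovery (Hz; negative:
#'   median-frequency decline persists after exhaustion).
#' @param class3_amp_drift fractional amplitude change during recovery.
#' @param target_channels channels receiving the class-dependent effects
#'   (default the two VL channels).
#' @param amp burst amplitude scale (microvolts).
#' @param noise_floor_frac background white-noise amplitude as a fraction of
#'   `amp`.
#' @param lactate_slopes segment slopes (mmol/L/min) for the aerobic,
#'   accumulation and recovery phases.
#' @param lactate_breaks true breakpoints t' and t'' (s).
#' @param lactate_baseline resting lactate (mmol/L).
#' @param lactate_sigma measurement noise SD (mmol/L; point-of-care analyzer
#'   variability).
#' @param lactate_interval sampling interval (s; lactate drawn every two
#'   minutes).
#' @param channels channels to synthesize.
#' @param seed master seed for the session.
#' @return a `session_spec` list.
#' @export
session_spec <- function(duration = 1800, fs = 1926,
                         stride_period = 1.1, stride_jitter = 0.02,
                         offsets = c(BF = 0, VM = 0.15, VL = 0.30,
                                     SM = 0.05, GM = 0.40),
                         duty = 0.3, ramp = 0.05,
                         carrier_lo = 60, carrier_hi = 140,
                         class2_shift_hz = 15, class2_amp_drift = 0.20,
                         class3_shift_hz = -10, class3_amp_drift = 0.10,
                         target_channels = c("RVL", "LVL"),
                         amp = 100, noise_floor_frac = 0.05,
                         lactate_slopes = c(0.05, 0.35, -0.20),
                         lactate_breaks = c(720, 1440),
                         lactate_baseline = 1.2, lactate_sigma = 0.3,
                         lactate_interval = 120,
                         channels = MUSCLE_CHANNELS, seed = 42) {
  if (!(0 < lactate_breaks[1] && lactate_breaks[1] < lactate_breaks[2] &&
        lactate_breaks[2] < duration))
    stop_with("spec_error", "need 0 < t' < t'' < duration")
  if (duty <= 0 || duty >= 1) stop_with("spec_error", "duty must be in (0,1)")
  if (carrier_hi + max(class2_shift_hz, 0) >= fs / 2)
    stop_with("spec_error", "carrier band must stay below Nyquist")
  structure(as.list(environment()), class = "session_spec")
}

# noiseless lactate line of a spec, vectorized over t (seconds)
#' @noRd
lactate_truth <- function(spec, t) {
  s <- spec$lactate_slopes / 60  # mmol/L/s
  t1 <- spec$lactate_breaks[1]; t2 <- spec$lactate_breaks[2]
  spec$lactate_baseline + s[1] * pmin(t, t1) +
    s[2] * pmin(pmax(t - t1, 0), t2 - t1) +
    s[3] * pmax(t - t2, 0)
}

#' Generate a synthetic lactate series with known breakpoints
#'
#' Samples the connected three-segment line at the spec's sampling interval,
#' adds i.i.d. Gaussian measurement noise and clips at zero.
#'
#' @param spec a [session_spec()].
#' @return list: `series` (a [lactate_series()]), `t_prime`, `t_dprime`
#'   (ground truth, s), `truth` (noiseless values).
#' @export
gen_lactate_profile <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  times <- seq(0, spec$duration, by = spec$lactate_interval)
  t1 <- spec$lactate_breaks[1]; t2 <- spec$lactate_breaks[2]
  if (sum(times <= t1) < 2L || sum(times > t1 & times <= t2) < 2L ||
      sum(times > t2) < 2L)
    stop_with("spec_error",
              "breakpoints must be bracketed by >= 2 samples per segment")
  truth <- lactate_truth(spec, times)
  set.seed(derive_seed(spec$seed, 101))
  values <- pmax(truth + stats::rnorm(length(times), 0, spec$lactate_sigma), 0)
  list(series = lactate_series(times, values),
       t_prime = t1, t_dprime = t2, truth = truth)
}

# cosine-tapered gate added in place: rise centered at A, fall centered at D
#' @noRd
add_gate <- function(gate, A, D, ramp, fs) {
  n <- length(gate)
  i0 <- max(1L, floor((A - ramp / 2) * fs) + 1L)
  i1 <- min(n, floor((D + ramp / 2) * fs) + 1L)
  if (i1 <= i0) return(gate)
  t <- (seq(i0, i1) - 1) / fs
  g <- rep(1, length(t))
  ru <- t < A + ramp / 2
  g[ru] <- 0.5 - 0.5 * cos(pi * (t[ru] - (A - ramp / 2)) / ramp)
  rd <- t > D - ramp / 2
  g[rd] <- pmin(g[rd], 0.5 + 0.5 * cos(pi * (t[rd] - (D - ramp / 2)) / ramp))
  gate[i0:i1] <- pmax(gate[i0:i1], g)
  gate
}

# band-limited Gaussian noise via causal order-4 Butterworth pair
#' @noRd
band_noise <- function(n, fs, lo, hi) {
  w <- stats::rnorm(n)
  w <- sos_filter(butter_sos(4, lo, fs, "highpass"), w)
  w <- sos_filter(butter_sos(4, hi, fs, "lowpass"), w)
  w / stats::sd(w)
}

#' Generate a synthetic multichannel sEMG session
#'
#' Each channel is a train of cosine-gated band-limited Gaussian-noise
#' bursts at the stride period with the muscle's phase offset; all channels
#' share the same jittered stride clock. During the anaerobic phase the
#' target (VL) channels' carrier band shifts up by `class2_shift_hz` and
#' their amplitude rises by `class2_amp_drift`; during recovery the class-3
#' parameters apply. A ground-truth event table records every burst.
#'
#' @param spec a [session_spec()].
#' @return list: `recording` (a [recording()]), `events` (data.frame
#'   `channel`, `A`, `D`, `class`), `spec`.
#' @export
gen_semg_session <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  fs <- spec$fs
  n <- round(spec$duration * fs)
  tfit <- list(t_prime = spec$lactate_breaks[1],
               t_dprime = spec$lactate_breaks[2])
  # shared stride clock
  set.seed(derive_seed(spec$seed, 202))
  n_cycles <- ceiling(spec$duration / spec$stride_period) + 2L
  periods <- spec$stride_period *
    (1 + spec$stride_jitter * stats::rnorm(n_cycles))
  starts <- 0.2 + cumsum(c(0, periods[-n_cycles]))
  keep <- starts + periods < spec$duration - spec$ramp
  starts <- starts[keep]; periods <- periods[keep]
  t_samp <- (seq_len(n) - 1) / fs
  cls_samp <- assign_classes(tfit, t_samp)
  chans <- list(); events <- list()
  for (ci in seq_along(spec$channels)) {
    ch <- spec$channels[ci]
    muscle <- substring(ch, 2)
    leg <- substring(ch, 1, 1)
    off <- spec$offsets[[muscle]] + if (leg == "L") 0.5 else 0
    A <- starts + off * periods
    D <- A + spec$duty * periods
    ok <- D + spec$ramp / 2 < spec$duration
    A <- A[ok]; D <- D[ok]
    gate <- numeric(n)
    for (k in seq_along(A)) gate <- add_gate(gate, A[k], D[k], spec$ramp, fs)
    set.seed(derive_seed(spec$seed, 300 + ci))
    base <- band_noise(n, fs, spec$carrier_lo, spec$carrier_hi)
    if (ch %in% spec$target_channels) {
      c2 <- band_noise(n, fs, spec$carrier_lo + spec$class2_shift_hz,
                       spec$carrier_hi + spec$class2_shift_hz)
      c3 <- band_noise(n, fs, spec$carrier_lo + spec$class3_shift_hz,
                       spec$carrier_hi + spec$class3_shift_hz)
      carrier <- base * (cls_samp == 1) +
        (1 + spec$class2_amp_drift) * c2 * (cls_samp == 2) +
        (1 + spec$class3_amp_drift) * c3 * (cls_samp == 3)
    } else {
      carrier <- base
    }
    floor_noise <- spec$noise_floor_frac * stats::rnorm(n)
    chans[[ch]] <- spec$amp * (gate * carrier + floor_noise)
    events[[ch]] <- data.frame(
      channel = ch, A = A, D = D,
      class = assign_classes(tfit, (A + D) / 2))
  }
  list(recording = recording(chans, fs = fs),
       events = do.call(rbind, events), spec = spec)
}

#' Jittered per-participant session specs
#'
#' Derives `n` participant specs from a base spec: stride period, lactate
#' breakpoints, slopes and baseline are jittered from participant-indexed
#' sub-seeds, emulating between-runner variability in a cohort.
#'
#' @param n number of participants.
#' @param master_seed integer master seed.
#' @param base_spec a [session_spec()] giving the cohort-level defaults.
#' @param break_jitter max breakpoint perturbation (s, uniform, default 180).
#' @param slope_jitter max fractional slope perturbation (default 0.2).
#' @param period_jitter max fractional stride-period perturbation
#'   (default 0.08).
#' @return list of `n` [session_spec()] objects.
#' @export
participant_specs <- function(n, master_seed, base_spec = session_spec(),
                              break_jitter = 180, slope_jitter = 0.2,
                              period_jitter = 0.08) {
  # jittered breakpoints must stay bracketable by the lactate sampling grid
  # (>= 2 observations per segment, the generator's own requirement)
  times <- seq(0, base_spec$duration, by = base_spec$lactate_interval)
  admissible <- function(br) {
    br[1] > 0 && br[1] < br[2] && br[2] < base_spec$duration &&
      sum(times <= br[1]) >= 2 &&
      sum(times > br[1] & times <= br[2]) >= 2 &&
      sum(times > br[2]) >= 2
  }
  if (!admissible(base_spec$lactate_breaks))
    stop_with("spec_error",
              "base spec breakpoints are not bracketable by its lactate grid")
  lapply(seq_len(n), function(i) {
    set.seed(derive_seed(master_seed, 9000 + i))
    bj <- break_jitter
    br <- base_spec$lactate_breaks
    for (try in 1:30) {
      cand <- base_spec$lactate_breaks + stats::runif(2, -bj, bj)
      if (admissible(cand)) { br <- cand; break }
      bj <- bj / 2
    }
    sp <- base_spec
    sp$seed <- derive_seed(master_seed, i)
    sp$stride_period <- base_spec$stride_period *
      (1 + stats::runif(1, -period_jitter, period_jitter))
    sp$lactate_breaks <- br
    sp$lactate_slopes <- base_spec$lactate_slopes *
      (1 + stats::runif(3, -slope_jitter, slope_jitter))
    sp$lactate_baseline <- base_spec$lactate_baseline +
      stats::runif(1, -0.2, 0.2)
    sp
  })
}

#' Generate a full synthetic cohort
#'
#' Materializes recordings and lactate series for every participant spec.
#' At full session length a 10-channel recording is ~280 MB, so prefer
#' iterating over [participant_specs()] and discarding each session after
#' feature extraction when n is large.
#'
#' @param n_participants cohort size.
#' @param master_seed integer master seed.
#' @param base_spec cohort-level [session_spec()].
#' @param ... passed to [participant_specs()].
#' @return list of per-participant lists: `spec`, `semg` (from
#'   [gen_semg_session()]), `lactate` (from [gen_lactate_profile()]).
#' @export
gen_dataset <- function(n_participants, master_seed,
                        base_spec = session_spec(), ...) {
  specs <- participant_specs(n_participants, master_seed, base_spec, ...)
  lapply(specs, function(sp)
    list(spec = sp, semg = gen_semg_session(sp),
         lactate = gen_lactate_profile(sp)))
}
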