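#' Butterworth filter specification
#'
#' @param kind "lowpass" or "highpass".
#' @param order filter order (>= 1).
#' @param cutoff -3 dB cutoff frequency in Hz.
#' @param stated_stopband nominal stopband edge in Hz (informational).
#' @param stated_attenuation nominal stopband attenuation in dB (informational).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(kind = c("lowpass", "highpass"), order, cutoff,
                        stated_stopband = NA_real_,
                        stated_attenuation = NA_real_) {
  kind <- match.arg(kind)
  assert_scalar_num(order, "order"); assert_scalar_num(cutoff, "cutoff")
  if (order < 1) stop_with("config_error", "filter order must be >= 1")
  if (cutoff <= 0) stop_with("config_error", "cutoff must be > 0 Hz")
  structure(list(kind = kind, order = as.integer(order), cutoff = cutoff,
                 stated_stopband = stated_stopband,
                 stated_attenuation = stated_attenuation),
            class = "filter_spec")
}

# Butterworth design as cascaded second-order sections (biquads).
#
# The analog prototype poles are placed on the Butterworth circle, moved to
# the prewarped cutoff, transformed low->high where needed, and mapped to the
# z-plane with the bilinear transform one conjugate pair at a time. Designing
# in sections keeps the order-10 high-pass at 20 Hz / 1926 Hz numerically
# clean: the expanded transfer-function polynomial of that filter has poles
# at |z| ~ 0.99 and loses ~60 dB of dynamic range to coefficient rounding.
#' @noRd
butter_sos <- function(order, cutoff, fs, kind) {
  if (cutoff >= fs / 2)
    stop_with("config_error", "cutoff %g Hz must be below Nyquist %g Hz",
              cutoff, fs / 2)
  wc <- 2 * fs * tan(pi * cutoff / fs)          # prewarped analog cutoff rad/s
  k <- seq_len(order)
  p <- wc * exp(1i * pi * (2 * k + order - 1) / (2 * order)) # analog LP poles
  if (kind == "highpass") p <- wc^2 / p
  fs2 <- 2 * fs
  zd <- (fs2 + p) / (fs2 - p)                   # bilinear: digital poles
  # zeros: n at z=-1 (lowpass) or z=+1 (highpass)
  z0 <- if (kind == "highpass") 1 else -1
  # overall gain fixed at the passband reference point
  zeval <- if (kind == "highpass") -1 + 0i else 1 + 0i
  gain <- Mod(prod(zeval - zd)) / Mod(zeval - z0)^order
  # pair conjugate poles (and a real pole when the order is odd)
  pu <- zd[Im(zd) > 1e-14]
  preal <- Re(zd[abs(Im(zd)) <= 1e-14])
  secs <- lapply(pu, function(pp)
    list(b = c(1, -2 * z0, 1),
         a = Re(c(1, -2 * Re(pp), Mod(pp)^2))))
  if (length(preal))
    secs <- c(secs, lapply(preal, function(pp)
      list(b = c(1, -z0), a = c(1, -pp))))
  list(sections = secs, gain = gain, order = order, cutoff = cutoff,
       fs = fs, kind = kind)
}

# single-pass (causal) run of the biquad cascade
#' @noRd
sos_filter <- function(sos, x) {
  for (s in sos$sections) x <- as.numeric(signal::filter(s$b, s$a, x))
  x * sos$gain
}

# zero-phase (forward-backward) filtering. Start-up transients are
# suppressed two ways: odd-reflect padding sized to the filter's settling
# time (~3 periods of the cutoff), and removal of the edge value before each
# pass so the filter state does not see a step at t = 0 (the edge value is
# restored through the cascade's DC gain).
#' @noRd
sos_filtfilt <- function(sos, x) {
  n <- length(x)
  if (n <= 3L * sos$order)
    stop_with("insufficient_length",
              "channel of %d samples is shorter than 3x filter order", n)
  npad <- min(n - 1L,
              max(3L * sos$order * 2L + 6L,
                  ceiling(3 * sos$fs / sos$cutoff)))
  g_dc <- sos$gain * prod(vapply(sos$sections,
                                 function(s) sum(s$b) / sum(s$a), 0))
  one_pass <- function(v) {
    v0 <- v[1]
    sos_filter(sos, v - v0) + v0 * g_dc
  }
  head_pad <- 2 * x[1] - x[seq(npad + 1, 2)]
  tail_pad <- 2 * x[n] - x[seq(n - 1, n - npad)]
  xp <- c(head_pad, x, tail_pad)
  y <- one_pass(xp)
  y <- rev(one_pass(rev(y)))
  y[seq(npad + 1, npad + n)]
}

#' Analytic Butterworth magnitude response
#'
#' Gain in dB of the (single-pass) analog-prototype Butterworth response at
#' frequency `f`; the zero-phase application used by [bandlimit()] doubles
#' the dB values.
#'
#' @param spec a [filter_spec()].
#' @param f frequency (Hz), vectorized.
#' @return gain in dB (negative in the stopband).
#' @export
filter_response_db <- function(spec, f) {
  ratio <- if (spec$kind == "lowpass") f / spec$cutoff else spec$cutoff / f
  -10 * log10(1 + ratio^(2 * spec$order))
}

#' Band-limit an sEMG recording
#'
#' Applies the high-pass then the low-pass Butterworth filter to every
#' channel, zero-phase (forward-backward), so muscle activation timing is not
#' phase-shifted. Defaults are the order-10 pair used for treadmill sEMG:
#' 20 Hz high-pass (motion artifacts) and 400 Hz low-pass (electronic noise).
#'
#' @param rec a [recording()].
#' @param lp low-pass [filter_spec()].
#' @param hp high-pass [filter_spec()].
#' @return A filtered [recording()] of identical dimensions.
#' @export
bandlimit <- function(rec,
                      lp = filter_spec("lowpass", 10, 400, 450, 60),
                      hp = filter_spec("highpass", 10, 20, 10, 60)) {
  stopifnot(inherits(rec, "semg_recording"))
  if (!(hp$cutoff < lp$cutoff && lp$cutoff < rec$f_nyq))
    stop_with("config_error",
              "cutoffs must satisfy hp (%g) < lp (%g) < Nyquist (%g)",
              hp$cutoff, lp$cutoff, rec$f_nyq)
  sos_hp <- butter_sos(hp$order, hp$cutoff, rec$fs, "highpass")
  sos_lp <- butter_sos(lp$order, lp$cutoff, rec$fs, "lowpass")
  out <- rec$samples
  for (j in seq_len(ncol(out))) {
    y <- sos_filtfilt(sos_hp, out[, j])
    out[, j] <- sos_filtfilt(sos_lp, y)
  }
  recording(out, fs = rec$fs, channel_ids = rec$channel_ids)
}
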