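#' Frequency band grid
#'
#' The 19 overlapping 23.44 Hz-wide relative-power bands: band k spans
#' `[23.44 + (k-1)*11.72, 46.88 + (k-1)*11.72]` Hz, so the grid starts at
#' 23.44-46.88 Hz and ends at 234.4-257.8 Hz with an 11.72 Hz overlap
#' between neighbours.
#'
#' @return data.frame with columns `k`, `lo`, `hi` (Hz).
#' @export
band_grid <- function() {
  k <- 1:19
  data.frame(k = k, lo = 23.44 + (k - 1) * 11.72, hi = 46.88 + (k - 1) * 11.72)
}

#' Names of the 36 per-burst frequency features
#' @return character vector of length 36.
#' @export
freq_feature_names <- function() {
  c("RMS", "dRMS", "IF", "ModF", "MnF", "StD", "Skew", "Kurt",
    paste0("q_", seq(0.1, 0.9, by = 0.1)),
    paste0("p_band_", 1:19))
}

#' Magnitude spectrum of a burst
#'
#' One-sided magnitude spectrum |DFT| of the mean-removed burst at the native
#' bin spacing fs/N (no window). "Power" here is the magnitude of the DFT,
#' as is conventional for the distributive-power features downstream; a
#' squared-magnitude variant is available via `power`.
#'
#' @param samples burst samples (>= 32).
#' @param fs sampling rate (Hz).
#' @param power "magnitude" (default) or "squared".
#' @return list with `freqs` (Hz, ascending, 0..Nyquist) and `power`
#'   (non-negative), class `semg_spectrum`.
#' @export
burst_spectrum <- function(samples, fs, power = c("magnitude", "squared")) {
  power <- match.arg(power)
  n <- length(samples)
  if (n < 32L)
    stop_with("short_burst", "burst of %d samples is too short (< 32)", n)
  x <- samples - mean(samples)
  mag <- Mod(stats::fft(x))[seq_len(floor(n / 2) + 1L)]
  if (power == "squared") mag <- mag^2
  structure(list(freqs = (seq_len(floor(n / 2) + 1L) - 1L) * fs / n,
                 power = mag),
            class = "semg_spectrum")
}

#' Normalize a spectrum to a unit-integral frequency density
#'
#' Divides the spectrum by its trapezoidal integral over `[0, f_Nyq]` so that
#' the result integrates to 1 and can be treated as a probability density
#' over frequency (the "power distribution of frequencies").
#'
#' @param spec a [burst_spectrum()].
#' @return list with `freqs` (Hz) and `density` (1/Hz), class
#'   `semg_density`.
#' @export
normalize_spectrum <- function(spec) {
  stopifnot(inherits(spec, "semg_spectrum"))
  total <- trapz(spec$freqs, spec$power)
  if (total <= 0)
    stop_with("degenerate_spectrum", "all-zero spectrum cannot be normalized")
  structure(list(freqs = spec$freqs, density = spec$power / total),
            class = "semg_density")
}

# integral of the piecewise-linear density over [lo, hi] (exact)
#' @noRd
density_band_integral <- function(freqs, density, lo, hi) {
  lo <- max(lo, freqs[1]); hi <- min(hi, freqs[length(freqs)])
  if (hi <= lo) return(0)
  inner <- freqs[freqs > lo & freqs < hi]
  xs <- c(lo, inner, hi)
  ys <- stats::approx(freqs, density, xout = xs)$y
  trapz(xs, ys)
}

# smallest f with cumulative trapezoidal integral >= p. The density is
# piecewise linear, so the cumulative is piecewise quadratic; the within-bin
# crossing is solved exactly.
#' @noRd
density_quantile <- function(freqs, density, p) {
  cdf <- cumtrapz(freqs, density)
  cdf <- cdf / cdf[length(cdf)]
  j <- which(cdf >= p)[1]
  if (j == 1L) return(freqs[1])
  f0 <- freqs[j - 1]; f1 <- freqs[j]
  c0 <- cdf[j - 1]; c1 <- cdf[j]
  if (c1 <= c0) return(f1)
  h <- f1 - f0
  norm <- cumtrapz(freqs, density)[length(freqs)]
  d0 <- density[j - 1] / norm; d1 <- density[j] / norm
  a <- (d1 - d0) / (2 * h)        # C(f0 + u) = c0 + d0*u + a*u^2
  rhs <- p - c0
  u <- if (abs(a) < 1e-18) {
    if (d0 > 0) rhs / d0 else h
  } else {
    disc <- d0^2 + 4 * a * rhs
    if (disc < 0) disc <- 0
    (-d0 + sqrt(disc)) / (2 * a)
  }
  f0 + min(max(u, 0), h)
}

#' Spectral descriptors of one burst
#'
#' Computes the 36 frequency-domain features of a burst: time-domain RMS and
#' its backward difference dRMS, the instantaneous frequency IF
#' (zero crossings / (2 x duration)), and from the normalized density
#' the mode ModF, mean MnF, standard deviation StD, skewness, kurtosis, the
#' nine deciles q_0.1..q_0.9, and the 19 relative band powers of
#' [band_grid()].
#'
#' @param samples burst samples.
#' @param fs sampling rate (Hz).
#' @param prev_rms RMS of the previous burst of the same channel, or NA for
#'   the first burst (dRMS is then 0 by convention).
#' @param power spectrum convention, see [burst_spectrum()].
#' @return named numeric vector of length 36 (see [freq_feature_names()]).
#' @export
spectral_descriptors <- function(samples, fs, prev_rms = NA_real_,
                                 power = "magnitude") {
  spec <- burst_spectrum(samples, fs, power)
  ns <- normalize_spectrum(spec)
  f <- ns$freqs; d <- ns$density
  rms <- sqrt(mean(samples^2))
  drms <- if (is.na(prev_rms)) 0 else rms - prev_rms
  # zero crossings of the mean-removed burst; exact zeros count with the
  # following sample
  x <- samples - mean(samples)
  sg <- sign(x); sg[sg == 0] <- 1
  zc <- sum(sg[-1] != sg[-length(sg)])
  if_hz <- zc / (2 * (length(samples) / fs))
  modf <- f[which.max(d)]
  mnf <- trapz(f, f * d)
  v2 <- trapz(f, (f - mnf)^2 * d)
  std <- sqrt(max(v2, 0))
  skew <- if (std > 0) trapz(f, (f - mnf)^3 * d) / std^3 else 0
  kurt <- if (std > 0) trapz(f, (f - mnf)^4 * d) / std^4 else 0
  q <- vapply(seq(0.1, 0.9, by = 0.1),
              function(p) density_quantile(f, d, p), numeric(1))
  bg <- band_grid()
  pb <- vapply(seq_len(nrow(bg)), function(k)
    density_band_integral(f, d, bg$lo[k], bg$hi[k]), numeric(1))
  stats::setNames(c(rms, drms, if_hz, modf, mnf, std, skew, kurt, q, pb),
                  freq_feature_names())
}

#' Per-burst frequency feature matrix for one channel
#'
#' Applies [spectral_descriptors()] to every detected burst of a channel,
#' chaining dRMS across consecutive bursts. Bursts shorter than 32 samples
#' are skipped.
#'
#' @param samples preprocessed channel samples.
#' @param fs sampling rate (Hz).
#' @param bursts data.frame with `A`, `D` (s) from [detect_bursts()].
#' @param power spectrum convention.
#' @return data.frame: `t_mid_s` (burst midpoint) plus the 36 feature
#'   columns; zero rows if no usable burst.
#' @export
channel_freq_features <- function(samples, fs, bursts, power = "magnitude") {
  rows <- list()
  prev_rms <- NA_real_
  for (i in seq_len(nrow(bursts))) {
    i0 <- floor(bursts$A[i] * fs) + 1L
    i1 <- min(floor(bursts$D[i] * fs) + 1L, length(samples))
    if (i1 - i0 + 1L < 32L) next
    seg <- samples[i0:i1]
    feats <- spectral_descriptors(seg, fs, prev_rms, power)
    prev_rms <- feats[["RMS"]]
    rows[[length(rows) + 1L]] <-
      c(t_mid_s = (bursts$A[i] + bursts$D[i]) / 2, feats)
  }
  if (!length(rows))
    return(stats::setNames(
      as.data.frame(matrix(numeric(0), 0, 37)),
      c("t_mid_s", freq_feature_names())))
  as.data.frame(do.call(rbind, rows))
}
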