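#' Catmull-Rom cubic Hermite interpolation
#'
#' Piecewise-cubic Hermite interpolation with Catmull-Rom tangents: the
#' tangent at an interior knot i is the centered difference
#' (x[i+1] - x[i-1]) / (t[i+1] - t[i-1]); the two endpoints use one-sided
#' differences. The interpolant passes through every knot and is C1
#' continuous. Used both to resample the sparse blood-lactate series onto
#' sEMG feature timestamps and to evaluate filtered signals between samples.
#'
#' @param times knot abscissae, strictly increasing (seconds).
#' @param values knot ordinates (or a [lactate_series()] as first argument,
#'   see [interpolate_lactate()]).
#' @param query_times evaluation points, all within `[times[1], times[n]]`.
#' @return numeric vector of interpolated values at `query_times`.
#' @export
catmull_rom_interpolate <- function(times, values, query_times) {
  times <- as.numeric(times); values <- as.numeric(values)
  n <- length(times)
  if (n < 2L) stop_with("insufficient_data", "need at least 2 knots")
  if (any(diff(times) <= 0))
    stop_with("validation_error", "knot times must be strictly increasing")
  if (any(query_times < times[1] - 1e-12) || any(query_times > times[n] + 1e-12))
    stop_with("extrapolation_error",
              "query outside the knot range [%g, %g]", times[1], times[n])
  query_times <- pmin(pmax(query_times, times[1]), times[n])
  # knot tangents (dx/dt): centered differences inside, one-sided at ends
  m <- numeric(n)
  if (n > 2L) {
    idx <- 2:(n - 1)
    m[idx] <- (values[idx + 1] - values[idx - 1]) / (times[idx + 1] - times[idx - 1])
  }
  m[1] <- (values[2] - values[1]) / (times[2] - times[1])
  m[n] <- (values[n] - values[n - 1]) / (times[n] - times[n - 1])
  seg <- findInterval(query_times, times, rightmost.closed = TRUE)
  seg[seg >= n] <- n - 1L
  h <- times[seg + 1] - times[seg]
  u <- (query_times - times[seg]) / h
  # Hermite basis
  h00 <- 2 * u^3 - 3 * u^2 + 1
  h10 <- u^3 - 2 * u^2 + u
  h01 <- -2 * u^3 + 3 * u^2
  h11 <- u^3 - u^2
  h00 * values[seg] + h10 * h * m[seg] + h01 * values[seg + 1] + h11 * h * m[seg + 1]
}

#' Interpolate a lactate series at arbitrary times
#'
#' @param series a [lactate_series()].
#' @param query_times seconds, within the sampled range.
#' @return lactate values (mmol/L). Values are not clamped to be
#'   non-negative; cubic overshoot below zero is possible and reported via a
#'   message.
#' @export
interpolate_lactate <- function(series, query_times) {
  stopifnot(inherits(series, "lactate_series"))
  out <- catmull_rom_interpolate(series$times, series$values, query_times)
  if (any(out < 0))
    message(sprintf("lactate interpolant overshoots below 0 at %d point(s)",
                    sum(out < 0)))
  out
}

#' Interpolate a sampled signal at arbitrary times
#'
#' Catmull-Rom Hermite interpolation with knots at the sample instants
#' 0, 1/fs, 2/fs, ...
#'
#' @param samples numeric vector.
#' @param fs sampling rate (Hz).
#' @param query_times seconds, within `[0, (n-1)/fs]`.
#' @return interpolated values.
#' @export
interpolate_signal <- function(samples, fs, query_times) {
  if (!length(samples)) stop_with("insufficient_data", "empty signal")
  t <- (seq_along(samples) - 1) / fs
  catmull_rom_interpolate(t, samples, query_times)
}
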