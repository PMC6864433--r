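#' @keywords internal
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# cumulative trapezoidal integral, same length as x, starts at 0
#' @noRd
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2))
}

#' @noRd
stop_with <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "fatiguecps_error")))
}

#' @noRd
assert_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_with("config_error", "'%s' must be a finite numeric scalar", name)
  invisible(x)
}

# derive a 32-bit-safe stream seed from a master seed and an index
#' @noRd
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 7919 + as.numeric(index) * 104729) %% 2147483646) + 1L
}
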