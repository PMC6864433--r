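# design matrix for the connected three-piece line, linear in
# (a1, b1, b2, b3) once the breakpoints are fixed. Substituting the
# continuity constraints a2 = a1 + (b1 - b2)/t' and a3 = a2 + (b2 - b3)/t''
# into the piecewise form gives, per observation time t:
#   segment 1 (t <= t'):        a1*t + b1
#   segment 2 (t' < t <= t''):  a1*t + b1*(t/t') + b2*(1 - t/t')
#   segment 3 (t > t''):        a1*t + b1*(t/t') + b2*(t/t'' - t/t') +
#                               b3*(1 - t/t'')
#' @noRd
cps_design <- function(t, tp, td) {
  s1 <- t <= tp
  s3 <- t > td
  s2 <- !s1 & !s3
  cbind(a1 = t,
        b1 = ifelse(s1, 1, t / tp),
        b2 = ifelse(s1, 0, ifelse(s2, 1 - t / tp, t / td - t / tp)),
        b3 = ifelse(s3, 1 - t / td, 0))
}

#' Fit the connected three-segment piecewise-linear lactate model
#'
#' Searches all admissible breakpoint pairs (t', t'') on a candidate grid;
#' for each pair the continuity-constrained model is linear in
#' (a1, b1, b2, b3) and is solved by ordinary least squares; the pair with
#' the smallest sum of squared errors wins (ties: smallest t', then smallest
#' t''). t' is the lactate threshold, t'' the time of maximal lactate
#' accumulation at exhaustion.
#'
#' @param series a [lactate_series()] with at least 6 samples.
#' @param grid candidate breakpoint times (s). Defaults to the interior
#'   observation times; `refine > 1` inserts `refine - 1` evenly spaced
#'   candidates between consecutive observations.
#' @param refine integer grid-refinement factor (default 1 = observation
#'   times only).
#' @return object of class `cps_fit`: `t_prime`, `t_dprime`, slopes
#'   `a1, a2, a3` (mmol/L/s), intercepts `b1, b2, b3` (mmol/L), `sse`,
#'   `t_max`, `degenerate` flag, and `warning` (NULL, or a plausibility
#'   message when the slope pattern does not look like
#'   aerobic -> accumulation -> recovery, or "no distinct phases" when the
#'   data are colinear).
#' @export
fit_change_points <- function(series, grid = NULL, refine = 1L) {
  stopifnot(inherits(series, "lactate_series"))
  t <- series$times; x <- series$values; n <- length(t)
  if (n < 6L)
    stop_with("insufficient_data",
              "change-point fit needs >= 6 lactate samples, got %d", n)
  if (is.null(grid)) {
    grid <- t[2:(n - 1)]
    if (refine > 1L) {
      extra <- unlist(lapply(seq_len(n - 1L), function(i)
        t[i] + (t[i + 1] - t[i]) * seq_len(refine - 1L) / refine))
      grid <- sort(unique(c(grid, extra)))
    }
  }
  grid <- sort(unique(grid))
  grid <- grid[grid > t[1] & grid < t[n]]
  best <- NULL
  for (tp in grid) {
    if (sum(t <= tp) < 2L) next
    for (td in grid[grid > tp]) {
      if (sum(t > tp & t <= td) < 2L || sum(t > td) < 2L) next
      X <- cps_design(t, tp, td)
      qrX <- qr(X)
      theta <- qr.coef(qrX, x)
      deg <- qrX$rank < 4L
      if (deg) theta[is.na(theta)] <- 0
      resid <- x - X %*% theta
      sse <- sum(resid^2)
      if (is.null(best) || sse < best$sse * (1 - 1e-9) - 1e-12)
        best <- list(tp = tp, td = td, theta = theta, sse = sse,
                     degenerate = deg)
    }
  }
  if (is.null(best))
    stop_with("fitting_error",
              "no admissible breakpoint pair (need >= 2 samples per segment)")
  a1 <- best$theta[[1]]; b1 <- best$theta[[2]]
  b2 <- best$theta[[3]]; b3 <- best$theta[[4]]
  a2 <- a1 + (b1 - b2) / best$tp
  a3 <- a2 + (b2 - b3) / best$td
  warn <- NULL
  scale <- max(abs(c(a1, a2, a3)), .Machine$double.eps)
  if (abs(a2 - a1) < 1e-10 * scale && abs(a3 - a2) < 1e-10 * scale)
    warn <- "no distinct phases: segment slopes are indistinguishable"
  else if (a2 <= a1 || a3 >= 0)
    warn <- paste("implausible phase pattern: expected accumulation slope",
                  "above aerobic slope and negative recovery slope")
  structure(list(t_prime = best$tp, t_dprime = best$td,
                 a1 = a1, b1 = b1, a2 = a2, b2 = b2, a3 = a3, b3 = b3,
                 sse = best$sse, t_max = series$t_max,
                 degenerate = best$degenerate, warning = warn),
            class = "cps_fit")
}

#' @export
print.cps_fit <- function(x, ...) {
  cat(sprintf("<cps_fit> t' = %.1f s, t'' = %.1f s (t_max %.1f s), sse = %.4g\n",
              x$t_prime, x$t_dprime, x$t_max, x$sse))
  cat(sprintf("  slopes (mmol/L/min): %.3f, %.3f, %.3f\n",
              x$a1 * 60, x$a2 * 60, x$a3 * 60))
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' Evaluate the fitted piecewise line
#'
#' @param fit a [fit_change_points()] result.
#' @param t times (s) within `[0, t_max]`.
#' @return fitted lactate values (mmol/L); segment 1 on `[0, t']`, segment 2
#'   on `(t', t'']`, segment 3 on `(t'', t_max]` (boundaries belong to the
#'   earlier segment).
#' @export
evaluate_piecewise <- function(fit, t) {
  stopifnot(inherits(fit, "cps_fit"))
  if (any(t < -1e-9) || any(t > fit$t_max + 1e-9))
    stop_with("extrapolation_error", "t outside [0, %g]", fit$t_max)
  ifelse(t <= fit$t_prime, fit$a1 * t + fit$b1,
         ifelse(t <= fit$t_dprime, fit$a2 * t + fit$b2,
                fit$a3 * t + fit$b3))
}

#' Assign fatigue-phase classes to timestamps
#'
#' Class 1 (aerobic) on `[0, t']`, class 2 (anaerobic / lactate accumulation)
#' on `(t', t'']`, class 3 (recovery) on `(t'', t_max]`; breakpoints belong
#' to the earlier phase.
#'
#' @param fit a [fit_change_points()] result (or any list with `t_prime`,
#'   `t_dprime`).
#' @param timestamps times (s).
#' @return integer vector of classes in {1, 2, 3}.
#' @export
assign_classes <- function(fit, timestamps) {
  ifelse(timestamps <= fit$t_prime, 1L,
         ifelse(timestamps <= fit$t_dprime, 2L, 3L))
}
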