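# Independent oracles used across test files. Each reimplements the checked
# quantity by a different route than the package code.

# naive O(N^2) one-sided DFT magnitude of a mean-removed signal
naive_dft_magnitude <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  k <- 0:floor(n / 2)
  vapply(k, function(kk) {
    w <- -2 * pi * kk * (0:(n - 1)) / n
    Mod(sum(x * complex(real = cos(w), imaginary = sin(w))))
  }, numeric(1))
}

# Hermite basis-polynomial evaluation at a single query inside knot segment
hermite_basis_eval <- function(times, values, tq) {
  n <- length(times)
  m <- numeric(n)
  for (i in seq_len(n)) {
    if (i == 1) m[i] <- (values[2] - values[1]) / (times[2] - times[1])
    else if (i == n) m[i] <- (values[n] - values[n - 1]) / (times[n] - times[n - 1])
    else m[i] <- (values[i + 1] - values[i - 1]) / (times[i + 1] - times[i - 1])
  }
  seg <- max(which(times <= tq)); seg <- min(seg, n - 1)
  h <- times[seg + 1] - times[seg]
  u <- (tq - times[seg]) / h
  h00 <- (1 + 2 * u) * (1 - u)^2
  h10 <- u * (1 - u)^2
  h01 <- u^2 * (3 - 2 * u)
  h11 <- u^2 * (u - 1)
  h00 * values[seg] + h10 * h * m[seg] + h01 * values[seg + 1] + h11 * h * m[seg + 1]
}

# exhaustive change-point search: every admissible pair solved by explicit
# normal equations
brute_force_cps <- function(times, values, grid = NULL) {
  n <- length(times)
  if (is.null(grid)) grid <- times[2:(n - 1)]
  grid <- sort(unique(grid[grid > times[1] & grid < times[n]]))
  best <- list(sse = Inf)
  for (tp in grid) for (td in grid[grid > tp]) {
    if (sum(times <= tp) < 2 || sum(times > tp & times <= td) < 2 ||
        sum(times > td) < 2) next
    X <- cbind(times,
               ifelse(times <= tp, 1, times / tp),
               ifelse(times <= tp, 0,
                      ifelse(times <= td, 1 - times / tp,
                             times / td - times / tp)),
               ifelse(times > td, 1 - times / td, 0))
    th <- tryCatch(solve(t(X) %*% X, t(X) %*% values),
                   error = function(e) NULL)
    if (is.null(th)) next
    sse <- sum((values - X %*% th)^2)
    if (sse < best$sse - 1e-12) best <- list(sse = sse, tp = tp, td = td)
  }
  best
}

# pairwise Mann-Whitney AUC with ties counted one half
pairwise_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# second implementation of the spectral descriptors from a given density,
# via explicit loops over bins (same trapezoidal convention, different code)
loop_density_moments <- function(f, d) {
  nb <- length(f)
  tz <- function(y) {
    s <- 0
    for (i in 2:nb) s <- s + (f[i] - f[i - 1]) * (y[i] + y[i - 1]) / 2
    s
  }
  mn <- tz(f * d)
  v <- tz((f - mn)^2 * d)
  list(mnf = mn, std = sqrt(v),
       skew = tz((f - mn)^3 * d) / sqrt(v)^3,
       kurt = tz((f - mn)^4 * d) / v^2)
}

# small two-channel test session: returns a deterministic recording with one
# known burst per channel
tiny_burst_signal <- function(fs = 1926, dur = 3, burst_at = 1.0,
                              burst_len = 0.3, f_lo = 60, f_hi = 140,
                              ramp = 0.05, seed = 1) {
  set.seed(seed)
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  w <- rnorm(n)
  w <- stats::filter(w, rep(1 / 4, 4), sides = 1)  # crude low-pass colouring
  w[is.na(w)] <- 0
  carrier <- sin(2 * pi * 100 * t) + 0.3 * rnorm(n)
  gate <- rep(0, n)
  a0 <- burst_at - ramp / 2; d0 <- burst_at + burst_len
  ru <- t >= a0 & t <= burst_at + ramp / 2
  gate[ru] <- 0.5 - 0.5 * cos(pi * (t[ru] - a0) / ramp)
  mid <- t > burst_at + ramp / 2 & t < d0 - ramp / 2
  gate[mid] <- 1
  rd <- t >= d0 - ramp / 2 & t <= d0 + ramp / 2
  gate[rd] <- 0.5 + 0.5 * cos(pi * (t[rd] - (d0 - ramp / 2)) / ramp)
  gate * carrier
}

# compact cohort settings reused by the end-to-end checks: full 12-runner
# cohort with the class-dependent VL effects, session scaled to 960 s so the
# pooled forest stays tractable on one CPU
cohort_base_spec <- function() {
  session_spec(duration = 960, lactate_breaks = c(360, 720),
               channels = "RVL", target_channels = c("RVL", "LVL"))
}
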