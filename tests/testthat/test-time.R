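mk_cycle <- function(start = 0, end = 1, ...) {
  ev <- list(...)
  cy <- data.frame(start = start, end = end, duration = end - start)
  for (m in c("RBF", "RVM", "RVL", "LBF", "LVM", "LVL")) {
    a <- if (!is.null(ev[[m]])) ev[[m]][1] else NA_real_
    d <- if (!is.null(ev[[m]])) ev[[m]][2] else NA_real_
    cy[[paste0("A_", m)]] <- a
    cy[[paste0("D_", m)]] <- d
  }
  cy$complete <- !anyNA(cy)
  cy
}

full_cycle <- function(start = 0, end = 1) {
  p <- end - start
  mk_cycle(start, end,
           RBF = start + c(0, 0.3) * p, RVM = start + c(0.15, 0.45) * p,
           RVL = start + c(0.30, 0.60) * p, LBF = start + c(0.50, 0.80) * p,
           LVM = start + c(0.65, 0.95) * p, LVL = start + c(0.80, 1.10) * p)
}

test_that("phase shift follows the activation-difference definition", {
  cy <- mk_cycle(0, 1, RBF = c(0, 0.3), RVM = c(0.10, 0.4), RVL = c(0.35, 0.7),
                 LBF = c(0.5, 0.8), LVM = c(0.6, 0.9), LVL = c(0.8, 0.99))
  expect_equal(phase_shift(cy, "RVM", "RVM"), 0)
  expect_equal(phase_shift(cy, "RVM", "RVL"), 0.25)
  expect_equal(phase_shift(cy, "RVL", "RVM"), -0.25)  # antisymmetry
  set.seed(31)
  for (i in 1:10) {
    cyr <- full_cycle(runif(1, 0, 5), runif(1, 6, 8))
    for (p in list(c("RBF", "RVL"), c("LVM", "LVL")))
      expect_equal(phase_shift(cyr, p[1], p[2]),
                   -phase_shift(cyr, p[2], p[1]), tolerance = 1e-12)
  }
  cym <- mk_cycle(0, 1, RBF = c(0, 0.3))
  expect_error(phase_shift(cym, "RBF", "RVL"), "missing")
})

test_that("active-time percentage is the burst fraction of the cycle", {
  cy <- mk_cycle(0, 1, RBF = c(0.1, 0.4))
  expect_equal(active_time_pct(cy, "RBF"), 0.3)
  cy2 <- mk_cycle(0, 2, RBF = c(0, 2))
  expect_equal(active_time_pct(cy2, "RBF"), 1.0)
})

test_that("cycle RMS matches direct sum-of-squares computation", {
  fs <- 1000
  x <- rep(2.5, 5000)
  expect_equal(cycle_rms(x, fs, 1, 2), 2.5, tolerance = 1e-12)
  t <- (0:4999) / fs
  s <- sin(2 * pi * 10 * t)
  expect_lt(abs(cycle_rms(s, fs, 1, 2) - 1 / sqrt(2)), 0.01)
  set.seed(32)
  z <- rnorm(5000)
  i0 <- floor(0.73 * fs) + 1; i1 <- floor(2.11 * fs) + 1
  expect_equal(cycle_rms(z, fs, 0.73, 2.11),
               sqrt(sum(z[i0:i1]^2) / (i1 - i0 + 1)), tolerance = 1e-12)
})

test_that("session aggregation produces the 51-entry vector with Table-style layout", {
  rows <- do.call(rbind, lapply(0:4, function(i) {
    rec <- recording(list(RBF = rep(1, 10)), fs = 10)  # placeholder unused
    cy <- full_cycle(i, i + 1)
    r <- data.frame(t_s = i)
    for (p in fatiguecps:::PHASE_PAIRS)
      r[[paste0("phi_", p[1], "_", p[2])]] <- phase_shift(cy, p[1], p[2])
    for (m in fatiguecps:::STRIDE_MUSCLES)
      r[[paste0("alpha_", m)]] <- active_time_pct(cy, m)
    for (m in fatiguecps:::STRIDE_MUSCLES)
      r[[paste0("rho_", m)]] <- 1 + 0.1 * i
    r
  }))
  v <- aggregate_session(rows)
  expect_length(v, 51L)
  expect_identical(names(v), time_feature_names())
  expect_length(time_event_indices(), 36L)
  # time-event subset excludes every amplitude-derived entry
  te <- names(v)[time_event_indices()]
  expect_false(any(grepl("rho", te)))
  # identical legs (by construction) give zero phase/alpha asymmetries
  expect_equal(unname(v["asym_phi_BF_VM"]), 0, tolerance = 1e-12)
  expect_equal(unname(v["asym_alpha_VL"]), 0, tolerance = 1e-12)
  expect_true(all(v[grep("_sd$", names(v))] >= 0))
})

test_that("mean and SD agree with the hand case (1,2,3)", {
  rows <- do.call(rbind, lapply(1:3, function(i) {
    r <- full_cycle(i, i + 1)
    out <- data.frame(t_s = i)
    for (p in fatiguecps:::PHASE_PAIRS)
      out[[paste0("phi_", p[1], "_", p[2])]] <- i  # plant the values 1,2,3
    for (m in fatiguecps:::STRIDE_MUSCLES) out[[paste0("alpha_", m)]] <- 0.5
    for (m in fatiguecps:::STRIDE_MUSCLES) out[[paste0("rho_", m)]] <- 1
    out
  }))
  v <- aggregate_session(rows)
  expect_equal(unname(v["phi_RBF_RVM_am"]), 2)
  expect_equal(unname(v["phi_RBF_RVM_sd"]), 1)  # 1/(n-1) divisor
  expect_error(aggregate_session(rows[1, ]), "insufficient|>= 2")
})

test_that("asymmetries are invariant to swapping legs", {
  set.seed(33)
  rows <- do.call(rbind, lapply(1:6, function(i) {
    out <- data.frame(t_s = i)
    for (p in fatiguecps:::PHASE_PAIRS)
      out[[paste0("phi_", p[1], "_", p[2])]] <- rnorm(1)
    for (m in fatiguecps:::STRIDE_MUSCLES)
      out[[paste0("alpha_", m)]] <- runif(1, 0.2, 0.5)
    for (m in fatiguecps:::STRIDE_MUSCLES)
      out[[paste0("rho_", m)]] <- runif(1, 1, 3)
    out
  }))
  swap <- function(nm) {
    nm2 <- chartr("RL", "LR", nm)
    ifelse(nm2 %in% names(rows), nm2, nm)
  }
  rows_sw <- rows
  names(rows_sw) <- vapply(names(rows), swap, "")
  v <- aggregate_session(rows)
  v_sw <- aggregate_session(rows_sw[names(rows)])
  for (nm in grep("^asym_(alpha|rho)", names(v), value = TRUE))
    expect_equal(unname(v[nm]), unname(v_sw[nm]), tolerance = 1e-12)
})

test_that("windowed aggregation is consistent with whole-session output", {
  set.seed(34)
  rows <- do.call(rbind, lapply(1:25, function(i) {
    out <- data.frame(t_s = i)
    for (p in fatiguecps:::PHASE_PAIRS)
      out[[paste0("phi_", p[1], "_", p[2])]] <- rnorm(1)
    for (m in fatiguecps:::STRIDE_MUSCLES)
      out[[paste0("alpha_", m)]] <- runif(1, 0.2, 0.5) + 0.01 * i
    for (m in fatiguecps:::STRIDE_MUSCLES)
      out[[paste0("rho_", m)]] <- runif(1, 1, 3)
    out
  }))
  whole <- windowed_time_features(rows, window = 25, hop = 5)
  expect_equal(nrow(whole), 1L)
  expect_equal(unlist(whole[1, -1]), aggregate_session(rows),
               tolerance = 1e-12)
  win <- windowed_time_features(rows, window = 10, hop = 5)
  expect_equal(nrow(win), 4L)
  # drifting alpha gives monotone windowed means
  expect_true(all(diff(win$alpha_RVL_am) > 0))
  # constant rows give zero SD everywhere
  rows_c <- rows
  for (nm in setdiff(names(rows), "t_s")) rows_c[[nm]] <- 1
  win_c <- windowed_time_features(rows_c, window = 10, hop = 5)
  expect_true(all(abs(win_c[, grep("_sd$", names(win_c))]) < 1e-12))
})
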