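small_spec <- function(...) {
  session_spec(duration = 60, lactate_breaks = c(20, 40),
               lactate_interval = 5, channels = c("RBF", "RVL"), ...)
}

test_that("generators are deterministic under a fixed seed", {
  sp <- small_spec(seed = 42)
  l1 <- gen_lactate_profile(sp); l2 <- gen_lactate_profile(sp)
  expect_identical(l1$series$values, l2$series$values)
  s1 <- gen_semg_session(sp); s2 <- gen_semg_session(sp)
  expect_identical(s1$recording$samples, s2$recording$samples)
  expect_identical(s1$events, s2$events)
  sp2 <- small_spec(seed = 43)
  expect_false(identical(gen_lactate_profile(sp2)$series$values,
                         l1$series$values))
})

test_that("noiseless lactate lies on the line and is recovered exactly", {
  sp <- small_spec(lactate_sigma = 0, seed = 1)
  lac <- gen_lactate_profile(sp)
  expect_equal(lac$series$values, lac$truth, tolerance = 1e-12)
  fit <- fit_change_points(lac$series)
  expect_equal(fit$t_prime, lac$t_prime)
  expect_equal(fit$t_dprime, lac$t_dprime)
  expect_lt(fit$sse, 1e-12)
})

test_that("invalid specs are rejected", {
  expect_error(session_spec(lactate_breaks = c(1500, 700)), "t'")
  expect_error(session_spec(duty = 1.2), "duty")
  expect_error(session_spec(carrier_hi = 1000), "Nyquist")
  expect_error(gen_lactate_profile(
    session_spec(duration = 400, lactate_breaks = c(100, 300),
                 lactate_interval = 120)),
    "bracketed")
})

test_that("ground-truth burst classes match the class assignment rule", {
  sp <- small_spec(seed = 9)
  ses <- gen_semg_session(sp)
  tfit <- list(t_prime = sp$lactate_breaks[1], t_dprime = sp$lactate_breaks[2])
  mid <- (ses$events$A + ses$events$D) / 2
  expect_identical(ses$events$class, assign_classes(tfit, mid))
  expect_true(all(ses$events$A < ses$events$D))
})

test_that("detected activations match generator ground truth", {
  sp <- small_spec(seed = 12)
  ses <- gen_semg_session(sp)
  pre <- bandlimit(ses$recording)
  b <- detect_bursts(pre$samples[, "RVL"], sp$fs)
  truth <- ses$events[ses$events$channel == "RVL", ]
  err <- vapply(truth$A, function(a) min(abs(b$A - a)), 0)
  expect_lte(median(err), 0.02)
})

test_that("raising the carrier band raises the extracted mean frequency", {
  mnf_for <- function(lo, hi, seed) {
    sp <- session_spec(duration = 30, lactate_breaks = c(10, 20),
                       lactate_interval = 3, carrier_lo = lo, carrier_hi = hi,
                       channels = "RVL", target_channels = character(0),
                       seed = seed)
    ses <- gen_semg_session(sp)
    b <- detect_bursts(ses$recording$samples[, "RVL"], sp$fs)
    fm <- channel_freq_features(ses$recording$samples[, "RVL"], sp$fs, b)
    mean(fm$MnF)
  }
  m1 <- mnf_for(60, 140, 31)
  m2 <- mnf_for(120, 200, 31)
  m3 <- mnf_for(200, 280, 31)
  expect_lt(m1, m2)
  expect_lt(m2, m3)
})

test_that("class-2 spectral shift separates VL burst features; null generator does not", {
  # effect on: default +15 Hz shift, amplitude drift on
  sp <- session_spec(duration = 240, lactate_breaks = c(80, 160),
                     lactate_interval = 20, channels = "RVL", seed = 77)
  ses <- gen_semg_session(sp)
  b <- detect_bursts(ses$recording$samples[, "RVL"], sp$fs)
  fm <- channel_freq_features(ses$recording$samples[, "RVL"], sp$fs, b)
  cls <- assign_classes(list(t_prime = 80, t_dprime = 160), fm$t_mid_s)
  expect_gte(mean(fm$q_0.5[cls == 2]) - mean(fm$q_0.5[cls == 1]), 10)
  # null generator: no shift, no drift -> classes indistinguishable
  ps <- vapply(1:20, function(s) {
    spn <- session_spec(duration = 120, lactate_breaks = c(40, 80),
                        lactate_interval = 10, channels = "RVL",
                        class2_shift_hz = 0, class2_amp_drift = 0,
                        class3_shift_hz = 0, class3_amp_drift = 0, seed = s)
    sesn <- gen_semg_session(spn)
    bn <- detect_bursts(sesn$recording$samples[, "RVL"], spn$fs)
    fmn <- channel_freq_features(sesn$recording$samples[, "RVL"], spn$fs, bn)
    cln <- assign_classes(list(t_prime = 40, t_dprime = 80), fmn$t_mid_s)
    kruskal_wallis(fmn$q_0.5, cln)$p
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("participant specs are jittered but valid and reproducible", {
  specs <- participant_specs(12, 1, base_spec = small_spec())
  expect_length(specs, 12L)
  for (sp in specs) {
    expect_true(0 < sp$lactate_breaks[1])
    expect_true(sp$lactate_breaks[1] < sp$lactate_breaks[2])
    expect_true(sp$lactate_breaks[2] < sp$duration)
  }
  periods <- vapply(specs, function(s) s$stride_period, 0)
  expect_gt(stats::sd(periods), 0)
  specs2 <- participant_specs(12, 1, base_spec = small_spec())
  expect_identical(specs, specs2)
  ds <- gen_dataset(2, 5, base_spec = small_spec())
  expect_length(ds, 2L)
  expect_false(identical(ds[[1]]$semg$recording$samples,
                         ds[[2]]$semg$recording$samples))
})
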