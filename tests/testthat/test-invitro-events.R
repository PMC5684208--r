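test_that("noise SD estimation: exact, contaminated, degenerate", {
  set.seed(1)
  x <- rnorm(20000, sd = 5)
  expect_lt(abs(estimate_noise_sd(x, 1000) - 5), 0.3)

  expect_equal(estimate_noise_sd(rep(3, 5000), 1000), 0)

  # sparse large events barely move the robust estimate
  g <- gen_sefp_trace(duration_s = 60, rate = 1000, noise_sd = 5,
                      events = data.frame(onset_s = seq(3, 57, by = 3),
                                          duration_ms = 40, amplitude_sd = 6),
                      seed = 4)
  expect_lt(abs(estimate_noise_sd(g$trace, g$rate) - 5) / 5, 0.10)

  expect_error(estimate_noise_sd(rnorm(100), 1000, window = c(0, 0.05)),
               "1 s")
})

test_that("sEFP detection: duration rule, ground truth, scale invariance", {
  g0 <- gen_sefp_trace(duration_s = 60, seed = 2)
  expect_equal(nrow(detect_sefp(g0$trace, g0$rate)), 0)

  # planted 30 ms 5-SD event detected with duration 30 +/- 4 ms;
  # planted 10 ms event excluded by the > 20 ms rule
  g <- gen_sefp_trace(duration_s = 60, noise_sd = 10,
                      events = data.frame(onset_s = c(10, 40),
                                          duration_ms = c(30, 10),
                                          amplitude_sd = c(5, 5)),
                      seed = 5)
  ev <- detect_sefp(g$trace, g$rate)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$duration_ms - 30), 4)
  expect_lt(abs(ev$onset_s - 10), 0.01)
  expect_gte(abs(ev$peak_sd), 3)

  # detector output invariant under amplitude rescaling of the trace
  ev2 <- detect_sefp(7.7 * g$trace, g$rate)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$duration_ms, ev$duration_ms, tolerance = 1e-9)
  expect_equal(ev2$peak_sd, ev$peak_sd, tolerance = 1e-6)

  # event frequency bookkeeping: events/min over the recording length
  expect_equal(attr(ev, "frequency_per_min"), 1 / 1)
})

test_that("fEPSP slope: ramp, linearity, alpha-function oracle", {
  rate <- 20000
  # ideal linear ramp of rate r after the blanking window
  sweep <- c(rep(0, 60), seq(0, -3, length.out = 121), seq(-3, 0, length.out = 200))
  r_true <- -3 / (120 / rate * 1000)      # mV per ms
  s1 <- fepsp_slope(sweep, rate)
  expect_equal(s1, r_true, tolerance = 0.02 * abs(r_true))

  # scaling the sweep scales the slope
  expect_equal(fepsp_slope(2 * sweep, rate), 2 * s1, tolerance = 1e-9)

  # alpha function f(t) = -A (t/tau) exp(1 - t/tau): the 10-90% chord slope
  # has a closed form computed here independently of the implementation
  tau <- 2e-3
  tt <- seq(0, 0.03, by = 1 / rate)
  alpha <- function(t) ifelse(t < 0, 0, -(t / tau) * exp(1 - t / tau))
  sweep2 <- c(rep(0, 60), alpha(tt))
  shape <- function(u) u * exp(1 - u)     # peak 1 at u = 1
  u10 <- uniroot(function(u) shape(u) - 0.1, c(1e-9, 1))$root
  u90 <- uniroot(function(u) shape(u) - 0.9, c(1e-9, 1))$root
  chord <- -(0.9 - 0.1) / ((u90 - u10) * tau * 1000)   # native units per ms
  s2 <- fepsp_slope(sweep2, rate)
  # least-squares slope over the 10-90% limb vs analytic chord: within 8%
  expect_lt(abs(s2 - chord) / abs(chord), 0.08)

  expect_error(fepsp_slope(rep(0, 1000), rate), "deflection")
})

test_that("LTP analysis: normalization contract and generator closure", {
  tm <- seq(-15, 60, by = 0.25)
  sl <- rep(-0.2, length(tm))
  la <- ltp_analyze(tm, sl)
  expect_equal(la$mean_potentiation, 100, tolerance = 1e-9)
  expect_equal(mean(la$norm_slope[tm < 0]), 100, tolerance = 1e-9)

  # window inside baseline-equal region still 100
  la2 <- ltp_analyze(tm, sl, window = c(0, 10))
  expect_equal(la2$mean_potentiation, 100)

  # multiplying all sweeps by a constant leaves the normalized series alone
  la3 <- ltp_analyze(tm, 5 * sl)
  expect_equal(la3$norm_slope, la$norm_slope)

  # generator closure at the two reported plateau levels
  for (pl in c(140, 190)) {
    g <- gen_ltp_series(plateau_pct = pl, seed = pl + 1)
    expect_lt(abs(ltp_analyze(g$time_min, g$slopes)$mean_potentiation - pl), 5)
  }

  expect_error(ltp_analyze(seq(-10, 60, 0.25), rnorm(281)), "baseline")
  expect_error(ltp_analyze(tm, sl, window = c(70, 80)), "window")

  # group comparison plumbing: strong separation at the reported levels
  sa <- lapply(1:4, function(i) {
    g <- gen_ltp_series(plateau_pct = 190, noise_cv = 0.05, seed = 300 + i)
    ltp_analyze(g$time_min, g$slopes)
  })
  sb <- lapply(1:4, function(i) {
    g <- gen_ltp_series(plateau_pct = 140, noise_cv = 0.05, seed = 400 + i)
    ltp_analyze(g$time_min, g$slopes)
  })
  cmp <- ltp_compare(sa, sb)
  expect_equal(cmp$anova$df_den, 6)
  expect_lt(cmp$window_test$p.value, 0.01)
})

test_that("dF/F formula, background averaging and gain invariance", {
  expect_equal(dff(c(2, 2, 2), 2, 1), c(0, 0, 0))
  expect_equal(dff(3, 2, 1), 100)
  expect_equal(dff(3, 2, list(c(1), c(1), c(1), c(1))), 100)
  expect_error(dff(3, 2, 2.5), "positive")

  # joint gain g on F, F0, B leaves dF/F unchanged
  f <- c(100, 120, 110); f0 <- 100; b <- c(20, 20, 20)
  expect_equal(dff(3 * f, 3 * f0, 3 * b), dff(f, f0, b), tolerance = 1e-12)

  # four background ROIs are averaged pointwise
  g <- gen_calcium_trace(transients = data.frame(onset_s = 5, amplitude = 30,
                                                 tau_s = 1),
                         noise_sd = 0, seed = 9)
  expect_equal(ncol(g$background_rois), 4)
  out <- dff(g$f, g$f0, g$background_rois)
  expect_lt(abs(max(out) - g$ground_truth$peak_dff), 1)
})
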