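test_that("tracking cleanup: speed deletion, gap interpolation, boxcar", {
  tt <- seq(0, 2, by = 0.02)
  n <- length(tt)

  # one sample jumping 3 cm in 20 ms (150 cm/s) is deleted then interpolated
  x <- rep(1, n); y <- seq(0, 10, length.out = n)   # ~5 cm/s drift
  x[51] <- x[51] + 3
  cl <- clean_tracking(data.frame(time = tt, x = x, y = y))
  expect_true(cl$valid[51])
  expect_lt(abs(cl$x[51] - 1), 0.2)

  # a 2 s gap stays invalid
  tt2 <- seq(0, 10, by = 0.02)
  x2 <- rep(1, length(tt2)); y2 <- rep(1, length(tt2))
  gap <- tt2 > 4 & tt2 < 6.2
  x2[gap] <- NA; y2[gap] <- NA
  cl2 <- clean_tracking(data.frame(time = tt2, x = x2, y = y2))
  expect_false(any(cl2$valid[gap]))

  # a 0.5 s gap is linearly interpolated
  gap3 <- tt2 > 4 & tt2 < 4.5
  x3 <- rep(seq_along(tt2) * 0.02, 1); y3 <- rep(0, length(tt2))
  x3[gap3] <- NA; y3[gap3] <- NA
  cl3 <- clean_tracking(data.frame(time = tt2, x = x3, y = y3))
  expect_true(all(cl3$valid[gap3]))
  expect_lt(max(abs(cl3$x[gap3] - seq_along(tt2)[gap3] * 0.02)), 1e-6)

  # constant input is a fixed point of the boxcar
  cl4 <- clean_tracking(data.frame(time = tt, x = rep(2, n), y = rep(3, n)))
  expect_equal(cl4$x, rep(2, n))
  expect_equal(cl4$y, rep(3, n))

  # cleaned series implies no speed above the threshold
  s <- gen_session(duration = 60, seed = 3)
  raw <- s$tracking
  raw$x[c(100, 900)] <- raw$x[c(100, 900)] + 5    # plant two jump artifacts
  spd <- compute_speed(clean_tracking(raw))
  expect_true(all(spd$speed[!is.na(spd$speed)] <= 100))

  expect_error(clean_tracking(data.frame(time = 1:3, x = rep(NA_real_, 3),
                                         y = rep(NA_real_, 3))), "valid")
})

test_that("speed computation on analytic paths", {
  tt <- seq(0, 1, by = 0.02)
  sp <- compute_speed(data.frame(time = tt, x = 10 * tt, y = 0))
  expect_true(all(abs(sp$speed[-1] - 10) < 1e-9))

  sp0 <- compute_speed(data.frame(time = tt, x = rep(1, length(tt)),
                                  y = rep(2, length(tt))))
  expect_true(all(sp0$speed == 0))

  # circular path: speed = r * omega
  r <- 5; om <- 2
  tt2 <- seq(0, 3, by = 0.002)
  spc <- compute_speed(data.frame(time = tt2, x = r * cos(om * tt2),
                                  y = r * sin(om * tt2)))
  expect_lt(max(abs(spc$speed[-1] - r * om)), 0.05)
})

test_that("band power: line spectrum, flat spectrum, normalization", {
  fs <- 250
  tt <- seq(0, 120 - 1 / fs, by = 1 / fs)
  speed <- data.frame(time = seq(0, 120, by = 0.02),
                      speed = rep(10, 6001))            # always in range
  # pure 7 Hz tone -> theta takes essentially all power
  bp <- band_percent_power(sin(2 * pi * 7 * tt), fs, speed)
  expect_gte(bp$percent[bp$band == "theta"], 99)
  expect_equal(sum(bp$percent), 100, tolerance = 1e-6)

  # white noise -> percents proportional to effective bandwidths
  widths <- c(3, 8, 18, 25, 55)
  expected <- 100 * widths / sum(widths)
  set.seed(2)
  devs <- replicate(25, {
    b <- band_percent_power(rnorm(length(tt)), fs, speed)
    b$percent - expected
  })
  expect_lt(max(abs(rowMeans(devs))), 2)

  expect_error(band_percent_power(rnorm(1000), fs, speed,
                                  bands = list(bad = c(0, 300))), "0-125")
})

test_that("speed filter excludes out-of-range LFP and notch removes 60 Hz", {
  fs <- 250
  n <- 120 * fs
  tt <- (seq_len(n) - 1) / fs
  ptime <- seq(0, 120, by = 0.02)
  # first half in range, second half out of range
  spd <- ifelse(ptime < 60, 10, 40)
  speed <- data.frame(time = ptime, speed = spd)
  x <- sin(2 * pi * 7 * tt)
  x[tt >= 60] <- x[tt >= 60] + 20 * sin(2 * pi * 25 * tt[tt >= 60])
  bp <- band_percent_power(x, fs, speed)
  # the huge out-of-range beta tone contributes nothing
  expect_gte(bp$percent[bp$band == "theta"], 99)
  expect_lte(bp$percent[bp$band == "beta"], 1)

  # 60 Hz tone is suppressed below 1% of its input band power
  x2 <- sin(2 * pi * 60 * tt) + 0.05 * rnorm(n)
  speed_all <- data.frame(time = ptime, speed = rep(10, length(ptime)))
  bp2 <- band_percent_power(x2, fs, speed_all, bands = c(default_bands(),
                                                         list(mains = c(55, 65))),
                            notch = NULL)
  bp2n <- band_percent_power(x2, fs, speed_all, bands = c(default_bands(),
                                                          list(mains = c(55, 65))))
  in_raw <- bp2$power[bp2$band == "mains"]
  in_notched <- bp2n$power[bp2n$band == "mains"]
  expect_lt(in_notched / in_raw, 0.01)

  expect_error(band_percent_power(rnorm(n), fs,
                                  data.frame(time = ptime, speed = rep(50, length(ptime)))),
               "in-range")
})

test_that("planted band fractions are recovered through the full chain", {
  s <- small_session(seed = 13, duration = 180)
  pct <- session_percents(s)
  planted <- 100 * s$ground_truth$band_fractions
  expect_lt(max(abs(pct[names(planted)] - planted)), 5)
})

test_that("group band comparison: identity, label swap and planted power", {
  s <- lapply(1:5, function(i) session_percents(small_session(seed = i, duration = 60)))
  tabs <- lapply(s, function(p) {
    structure(data.frame(band = names(p), percent = unname(p), power = unname(p)),
              class = c("band_power", "data.frame"))
  })
  # identical groups -> p = 1 under the zero-numerator convention
  same <- compare_bands(tabs[1:2], tabs[1:2])
  expect_true(all(same$p.value == 1))

  r_ab <- compare_bands(tabs[1:3], tabs[4:5])
  r_ba <- compare_bands(tabs[4:5], tabs[1:3])
  expect_equal(r_ab$t, -r_ba$t)
  expect_equal(r_ab$p.value, r_ba$p.value)

  # planted theta difference of 0.2 detected in >= 90% of runs at n = 5/4
  th_a <- c(delta = 0.25, theta = 0.35, beta = 0.15, low_gamma = 0.15,
            high_gamma = 0.10)
  th_b <- c(delta = 0.25, theta = 0.55, beta = 0.05, low_gamma = 0.08,
            high_gamma = 0.07)
  hits <- vapply(1:20, function(rep) {
    ta <- lapply(1:5, function(i) {
      p <- session_percents(gen_session(duration = 60, seed = 100 * rep + i,
                                        band_fractions = th_a))
      structure(data.frame(band = names(p), percent = unname(p), power = unname(p)),
                class = c("band_power", "data.frame"))
    })
    tb <- lapply(1:4, function(i) {
      p <- session_percents(gen_session(duration = 60, seed = 100 * rep + 50 + i,
                                        band_fractions = th_b))
      structure(data.frame(band = names(p), percent = unname(p), power = unname(p)),
                class = c("band_power", "data.frame"))
    })
    res <- compare_bands(ta, tb)
    res$p.value[res$band == "theta"] < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})
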