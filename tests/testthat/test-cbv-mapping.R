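test_that("dR2 formula, normalization and scale invariance", {
  d <- c(3, 3, 3)
  # Spre = Spost -> 0 everywhere
  m <- compute_cbv_map(array(5, d), array(5, d), te = 2)
  expect_true(all(m$values == 0))

  # single-voxel arithmetic: ln(e)/1 = 1
  m1 <- compute_cbv_map(array(exp(1), c(1, 1, 1)), array(1, c(1, 1, 1)), te = 1)
  expect_equal(as.numeric(m1$values), 1)

  # normalization divides by the vein mean
  spre <- array(exp(2), d); spost <- array(1, d)   # dR2 = 2 everywhere
  vein <- array(FALSE, d); vein[1, 1, 1] <- TRUE
  mn <- compute_cbv_map(spre, spost, te = 1, vein_roi = vein)
  expect_true(mn$normalized)
  expect_equal(mn$vein_mean, 2)
  expect_true(all(abs(mn$values - 1) < 1e-12))

  # common positive rescaling of both signals leaves the map unchanged
  g <- gen_cbv_volumes(n_per_group = c(1, 1), dims = d, seed = 8)
  p <- g$pairs[[1]]
  m_a <- compute_cbv_map(p$spre, p$spost, g$te)
  m_b <- compute_cbv_map(3.7 * p$spre, 3.7 * p$spost, g$te)
  expect_equal(m_a$values, m_b$values, tolerance = 1e-12)

  # errors: non-positive signal, empty vein
  expect_error(compute_cbv_map(array(-1, d), array(1, d), te = 1), "27 masked voxel")
  expect_error(compute_cbv_map(spre, spost, te = 1, vein_roi = array(FALSE, d)),
               "empty")
})

test_that("group t map matches the oracle and is antisymmetric", {
  one <- function(v) array(v, c(1, 1, 1))
  sm <- group_stat_map(lapply(1:3, one), lapply(4:6, one))
  expect_equal(as.numeric(sm$t), -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(as.numeric(sm$df), 4)

  sm_sw <- group_stat_map(lapply(4:6, one), lapply(1:3, one))
  expect_equal(as.numeric(sm_sw$t), -as.numeric(sm$t))

  # duplicated identical maps: zero-variance voxels become t = 0
  m <- array(2, c(2, 2, 2))
  sm0 <- group_stat_map(list(m, m), list(m, m))
  expect_true(all(sm0$t == 0))
  expect_true(all(sm0$zero_var))

  expect_error(group_stat_map(list(m), list(m, m)), "2 maps|length")
  expect_error(group_stat_map(list(m, m), list(m, array(1, c(3, 3, 3)))), "grid")
})

test_that("planted effect localizes the extreme t statistic", {
  hits <- vapply(1:40, function(seed) {
    g <- gen_cbv_volumes(n_per_group = c(7, 8), dims = c(10, 10, 8),
                         effect_size = 0.3, noise_sd = 0.1, seed = seed)
    m <- cbv_maps_by_group(g, normalize = FALSE)
    sm <- group_stat_map(m$A, m$B)
    g$effect_mask[which.max(abs(sm$t))]
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("cluster correction: threshold logic, defaults and monotonicity", {
  expect_equal(formals(cluster_correct)$n_iter, 10000L)

  g <- gen_cbv_volumes(n_per_group = c(6, 6), dims = c(10, 10, 6),
                       effect_size = 0.5, noise_sd = 0.1, smooth_fwhm = 1.5,
                       seed = 21)
  m <- cbv_maps_by_group(g, normalize = FALSE)
  sm <- group_stat_map(m$A, m$B)
  cs <- cluster_correct(sm, height_p = 0.01, n_iter = 300, seed = 1)
  # the planted effect survives and overlaps the planted region
  expect_gt(length(cs$sizes), 0)
  expect_true(any(g$effect_mask[cs$clusters[[1]]]))
  expect_true(all(cs$sizes >= cs$critical_size))
  # every member voxel passes the height threshold
  tcrit <- stats::qt(1 - 0.01 / 2, df = 10)
  expect_true(all(abs(sm$t[unlist(cs$clusters)]) >= tcrit))
  # stricter height -> no larger suprathreshold clusters
  cs_strict <- cluster_correct(sm, height_p = 0.001, n_iter = 300, seed = 1)
  expect_lte(max(c(0, cs_strict$all_cluster_sizes)),
             max(c(0, cs$all_cluster_sizes)))

  # degenerate map
  mm <- array(2, c(4, 4, 4))
  sm0 <- group_stat_map(list(mm, mm), list(mm, mm))
  expect_warning(cs0 <- cluster_correct(sm0, n_iter = 100), "degenerate")
  expect_length(cs0$sizes, 0)

  # no suprathreshold voxel -> empty set (null data, very strict height)
  g0 <- gen_cbv_volumes(n_per_group = c(3, 3), dims = c(4, 4, 4),
                        effect_size = 0, seed = 3)
  m0 <- cbv_maps_by_group(g0, normalize = FALSE)
  smn <- group_stat_map(m0$A, m0$B)
  csn <- cluster_correct(smn, height_p = 1e-7, n_iter = 100, seed = 2)
  expect_length(csn$sizes, 0)
})

test_that("permutation null is available and broadly agrees", {
  g <- gen_cbv_volumes(n_per_group = c(5, 5), dims = c(8, 8, 6),
                       effect_size = 0, noise_sd = 0.1, smooth_fwhm = 1.5,
                       seed = 31)
  m <- cbv_maps_by_group(g, normalize = FALSE)
  sm <- group_stat_map(m$A, m$B)
  cs_g <- cluster_correct(sm, n_iter = 200, seed = 1)
  cs_p <- cluster_correct(sm, n_iter = 200, seed = 1, null = "permutation",
                          maps_a = m$A, maps_b = m$B)
  expect_lt(abs(cs_g$critical_size - cs_p$critical_size), 6)
})

test_that("ROI summaries", {
  d <- c(3, 3, 2)
  m <- array(4, d)
  roi <- array(TRUE, d)
  s <- roi_summary(m, roi)
  expect_equal(s$mean, 4); expect_equal(s$sd, 0); expect_equal(s$n_voxels, 18)
  roi1 <- array(FALSE, d); roi1[2, 2, 1] <- TRUE
  m[2, 2, 1] <- 7
  expect_equal(roi_summary(m, roi1)$mean, 7)
  expect_error(roi_summary(m, array(FALSE, d)), "empty")
})

test_that("NIfTI round trip preserves a CBV map", {
  g <- gen_cbv_volumes(n_per_group = c(1, 1), dims = c(5, 4, 3), seed = 2)
  m <- compute_cbv_map(g$pairs[[1]]$spre, g$pairs[[1]]$spost, g$te)
  f <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(m, f)
  back <- read_volume_nifti(f)
  expect_equal(back, m$values, tolerance = 1e-6, ignore_attr = TRUE)
  unlink(f)
})
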