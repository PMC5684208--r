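mk_table <- function(n, mode = "positive", abund_max = 1000, n_samp = 6) {
  ab <- matrix(rep(seq_len(n), n_samp), n, n_samp)
  ab <- ab / max(ab) * abund_max
  df <- data.frame(feature_id = paste0("F", seq_len(n)), mode = mode,
                   mass = seq(100, 900, length.out = n),
                   rt = seq(1, 10, length.out = n))
  df[paste0("S", seq_len(n_samp))] <- as.data.frame(ab)
  df
}

test_that("feature filtering: top-2000 rule, 600-count floor, idempotence", {
  # 2500 features all above the floor -> exactly 2000 survive, the largest
  tab <- mk_table(2500, abund_max = 5000)
  f1 <- filter_features(tab)
  expect_equal(nrow(f1), 2000)
  expect_true(all(as.integer(sub("F", "", f1$feature_id)) > 500))

  # the floor is >= 600: max abundance 500 is dropped, exactly 600 is kept
  tab2 <- mk_table(3)
  tab2[paste0("S", 1:6)] <- 0
  tab2$S1 <- c(500, 600, 700)
  f2 <- filter_features(tab2)
  expect_setequal(f2$feature_id, c("F2", "F3"))

  # idempotence
  expect_equal(filter_features(f1), f1)

  # per-mode accounting
  tabm <- rbind(mk_table(50, "positive", 5000), mk_table(30, "negative", 5000))
  tabm$feature_id <- paste0("F", seq_len(80))
  f3 <- filter_features(tabm, top_n = 20)
  expect_equal(as.vector(table(f3$mode)[c("positive", "negative")]), c(20, 20))

  expect_warning(filter_features(mk_table(3, abund_max = 100)), "no feature")
})

test_that("targeted matching honours both tolerances and prefers nearest mass", {
  feats <- mk_table(1)
  feats$mass <- 200; feats$rt <- 5
  lib <- data.frame(name = c("in_both", "mass_out", "rt_out"),
                    mass = c(200.008, 200.012, 200.001),
                    rt = c(5.5, 5.1, 6.5),
                    mode = "positive")
  m <- match_targeted(feats, lib[1, ])
  expect_equal(m$metabolite, "in_both")
  expect_equal(m$dmass_mda, 8, tolerance = 1e-6)
  expect_true(is.na(match_targeted(feats, lib[2, ])$metabolite))
  expect_true(is.na(match_targeted(feats, lib[3, ])$metabolite))

  # nearest mass wins among joint candidates
  lib2 <- data.frame(name = c("far", "near"), mass = c(200.006, 200.003),
                     rt = c(5.2, 5.9), mode = "positive")
  expect_equal(match_targeted(feats, lib2)$metabolite, "near")

  # modes never cross
  libneg <- data.frame(name = "wrong_mode", mass = 200, rt = 5, mode = "negative")
  expect_true(is.na(match_targeted(feats, libneg)$metabolite))

  # generator closure: intended matches resolve, offset decoys never match
  gt <- gen_feature_table(n_features = 120, n_library = 40, n_offset = 8,
                          seed = 6)
  mm <- match_targeted(gt$features, gt$library)
  intended <- gt$ground_truth$matchable
  got <- stats::setNames(mm$metabolite, mm$feature_id)[names(intended)]
  expect_gte(mean(got == intended, na.rm = TRUE), 0.95)
  expect_false(any(gt$ground_truth$offset_names %in% got, na.rm = TRUE))
})

test_that("differential abundance: conventions, label swap, planted folds", {
  gt <- gen_feature_table(n_features = 60, affected = 1:10, fold_changes = 2,
                          n_low = 0, seed = 3)
  de <- differential_abundance(gt$features, gt$samples)
  expect_true(all(de$fold_change >= 1))
  expect_true(all(de$q.value >= de$p.value - 1e-12))
  aff <- de$feature_id %in% gt$ground_truth$affected_ids
  expect_true(all(de$regulation[aff] == "up"))

  # swapped labels flip direction, keep fold change and p
  de_sw <- differential_abundance(gt$features, gt$samples,
                                  group_a = "E4/4", group_b = "E3/3")
  expect_equal(de_sw$fold_change, de$fold_change)
  expect_equal(de_sw$p.value, de$p.value)
  expect_true(all(de_sw$regulation[aff] == "down"))

  # constant feature convention
  tabc <- mk_table(2, n_samp = 15)
  tabc[paste0("S", 1:15)] <- 1
  tabc[2, paste0("S", 1:15)] <- c(rep(1, 8), rep(3, 7))
  samc <- data.frame(sample = paste0("S", 1:15),
                     genotype = rep(c("E3/3", "E4/4"), c(8, 7)))
  dec <- differential_abundance(tabc, samc)
  expect_true(dec$constant[1])
  expect_equal(dec$p.value[1], 1)
  expect_false(dec$constant[2])

  expect_error(differential_abundance(tabc, data.frame(sample = c("S1", "S2"),
                                                       genotype = c("E3/3", "E4/4"))),
               "3 samples")

  # planted 2-fold features at n = 8 vs 7: median estimated fold near 2
  meds <- vapply(1:25, function(seed) {
    g <- gen_feature_table(n_features = 40, affected = 1:8, fold_changes = 2,
                           n_low = 0, seed = 500 + seed)
    d <- differential_abundance(g$features, g$samples)
    stats::median(d$fold_change[d$feature_id %in% g$ground_truth$affected_ids])
  }, 0)
  expect_gte(stats::median(meds), 1.7)
  expect_lte(stats::median(meds), 2.3)
})

test_that("BH family is per detection mode by default, poolable by flag", {
  gt <- gen_feature_table(n_features = 80, affected = 1:15, fold_changes = 3,
                          n_low = 0, seed = 9)
  de <- differential_abundance(gt$features, gt$samples)
  for (m in c("positive", "negative")) {
    ix <- de$mode == m
    expect_equal(de$q.value[ix], bh_fdr(de$p.value[ix]))
  }
  dep <- differential_abundance(gt$features, gt$samples, pool_modes = TRUE)
  expect_equal(dep$q.value, bh_fdr(de$p.value))
})
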