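test_that("label generation hits the requested disorder fraction and segment structure", {
  cfg0 <- generator_config(n_proteins = 20, disorder_fraction = 0, seed = 1)
  expect_true(all(unlist(generate_cohort(cfg0, NULL)$labels) == 0L))
  cfg1 <- generator_config(n_proteins = 20, disorder_fraction = 1, seed = 1)
  expect_true(all(unlist(generate_cohort(cfg1, NULL)$labels) == 1L))

  cfg <- generator_config(n_proteins = 200, disorder_fraction = 0.3,
                          mean_segment_length = 25, seed = 2)
  labs <- generate_cohort(cfg, NULL)$labels
  fractions <- vapply(labs, mean, numeric(1))
  se <- sd(fractions) / sqrt(length(fractions))
  expect_lt(abs(mean(fractions) - 0.3), 3 * se + 1e-9)
  # disorder occurs in runs: mean disordered segment length near the target
  seg_lens <- unlist(lapply(labs, function(l) {
    r <- rle(l); r$lengths[r$values == 1L]
  }))
  expect_gt(mean(seg_lens), 10)  # far from the i.i.d. value ~1.4

  expect_error(generate_labels(generator_config(mean_segment_length = 1)),
               "at least 2")
})

test_that("confidence profiles separate the states at the binormal rate", {
  # zero noise: a step profile, any threshold in (40, 90] separates perfectly
  cfg <- generator_config(n_proteins = 30, plddt_ordered = c(90, 0),
                          plddt_disordered = c(40, 0),
                          smoothing_window = 1, seed = 3)
  cohort <- generate_cohort(cfg, NULL)
  p <- unlist(cohort$plddt); l <- unlist(cohort$labels)
  expect_true(all(p[l == 0L] == 90) && all(p[l == 1L] == 40))

  # smoothing_window 1 leaves the draw untouched (identity check via moments)
  cfg2 <- generator_config(n_proteins = 5, smoothing_window = 1, seed = 4)
  cohort2 <- generate_cohort(cfg2, NULL)
  expect_gt(sd(unlist(cohort2$plddt)), 5)

  # binormal calibration: tpLD AUC ~ Phi(dprime / sqrt(2))
  for (dprime in c(1, 2)) {
    cfgd <- generator_config(n_proteins = 60, length_range = c(150, 250),
                             disorder_fraction = 0.5,
                             plddt_ordered = c(60, 5),
                             plddt_disordered = c(60 - dprime * 5, 5),
                             smoothing_window = 1, seed = 100 + dprime)
    ch <- generate_cohort(cfgd, NULL)
    lab <- unlist(ch$labels)
    auc <- roc_auc(lab, tpld_predict(unlist(ch$plddt)))$auc
    expect_lt(abs(auc - pnorm(dprime / sqrt(2))), 0.02)
  }
})

test_that("secondary-structure strings encode the discordance knobs", {
  cfg0 <- generator_config(n_proteins = 40, transient_helix_rate = 0,
                           confident_coil_rate = 0, seed = 5)
  cohort0 <- generate_cohort(cfg0, NULL)
  for (acc in names(cohort0$labels)) {
    expect_identical(dsspp_predict(cohort0$ss[[acc]]$ss8),
                     cohort0$labels[[acc]])
  }

  cfg3 <- generator_config(n_proteins = 40, transient_helix_rate = 0.3,
                           confident_coil_rate = 0, seed = 6)
  cohort3 <- generate_cohort(cfg3, NULL)
  miss <- unlist(lapply(names(cohort3$labels), function(acc) {
    dis <- cohort3$labels[[acc]] == 1L
    dsspp_predict(cohort3$ss[[acc]]$ss8)[dis] == 0L
  }))
  expect_lt(abs(mean(miss) - 0.3), 0.06)  # ~30% of disordered residues look helical
})

test_that("backbone construction is deterministic and respects the steric guard", {
  a <- generate_backbone(strrep("C", 25), seed = 9)
  b <- generate_backbone(strrep("C", 25), seed = 9)
  expect_identical(a$chains$A$CA, b$chains$A$CA)
  expect_gte(disbench:::min_nonadjacent_ca_dist(a$chains$A$CA), 2)
  helix <- generate_backbone(strrep("H", 20))
  # ideal geometry: consecutive CA-CA distance ~3.8 A
  d <- sqrt(rowSums(diff(helix$chains$A$CA)^2))
  expect_true(all(abs(d - 3.8) < 0.15))
})

test_that("coverage is biased toward ordered regions with the stated rates", {
  cfg <- generator_config(n_proteins = 150, length_range = c(80, 160),
                          coverage_fraction_ordered = 0.9,
                          coverage_fraction_disordered = 0.2, seed = 10)
  cohort <- generate_cohort(cfg, NULL)
  cov_ord <- c(); cov_dis <- c()
  for (acc in names(cohort$labels)) {
    lab <- cohort$labels[[acc]]
    covered <- disbench:::intervals_to_mask(cohort$coverage[[acc]]$intervals,
                                            length(lab))
    cov_ord <- c(cov_ord, covered[lab == 0L])
    cov_dis <- c(cov_dis, covered[lab == 1L])
  }
  se_o <- sqrt(0.9 * 0.1 / length(cov_ord))
  se_d <- sqrt(0.2 * 0.8 / length(cov_dis))
  expect_lt(abs(mean(cov_ord) - 0.9), 3 * se_o)
  expect_lt(abs(mean(cov_dis) - 0.2), 3 * se_d)
})

test_that("emulated predictor files hit their configured AUC", {
  cfg <- generator_config(n_proteins = 60, length_range = c(150, 250),
                          disorder_fraction = 0.5, seed = 11)
  cohort <- generate_cohort(cfg, predictor_aucs = c(perfect_sep = 0.98,
                                                    strong = 0.9,
                                                    chance = 0.5))
  lab <- unlist(cohort$labels)
  for (target in names(cohort$predictors)) {
    scores <- unlist(lapply(cohort$predictors[[target]], `[[`, "score"))
    expect_true(all(scores >= 0 & scores <= 1))
    got <- roc_auc(lab, scores)$auc
    want <- c(perfect_sep = 0.98, strong = 0.9, chance = 0.5)[[target]]
    expect_lt(abs(got - want), 0.02)
  }
})

test_that("identical configurations reproduce the cohort and its files byte for byte", {
  cfg <- generator_config(n_proteins = 10, length_range = c(40, 80), seed = 12)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$labels, c2$labels)
  expect_identical(c1$plddt, c2$plddt)
  expect_identical(c1$ss, c2$ss)
  expect_identical(c1$predictors, c2$predictors)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(c1, d1); write_cohort(c2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})
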