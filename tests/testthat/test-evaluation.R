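test_that("confusion counts treat disordered as the positive class and honour masks", {
  cm <- confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(cm, list(tp = 2L, fp = 0L, tn = 2L, fn = 0L))
  inv <- confusion(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(inv, list(tp = 0L, fp = 2L, tn = 0L, fn = 2L))
  masked <- confusion(c(1, 1, 1, 1, 0, 0, 0, 0), c(1, 0, 1, 0, 1, 0, 1, 0),
                      mask = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(masked$tp + masked$fp + masked$tn + masked$fn, 4L)
  expect_equal(masked, list(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
  expect_error(confusion(c(1, 0), c(1, 0, 1)), "lengths differ")
})

test_that("MCC matches hand evaluation and its degenerate conventions", {
  expect_equal(mcc(list(tp = 5L, fp = 0L, tn = 5L, fn = 0L)), 1)
  expect_equal(mcc(list(tp = 0L, fp = 5L, tn = 0L, fn = 5L)), -1)
  expect_equal(mcc(list(tp = 4L, fp = 2L, tn = 3L, fn = 1L)), 10 / sqrt(600))
  # all-positive calls with both classes present: zero factor -> 0
  expect_equal(mcc(list(tp = 5L, fp = 5L, tn = 0L, fn = 0L)), 0)
  # single-class reference: undefined, not 0
  expect_true(is.na(mcc(list(tp = 5L, fp = 0L, tn = 0L, fn = 5L))))
})

test_that("ROC AUC matches hand-counted concordance on worked examples", {
  perfect <- roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(perfect$auc, 1)
  # 3 of 4 positive-negative pairs concordant
  partial <- roc_auc(c(1, 1, 0, 0), c(0.9, 0.6, 0.65, 0.2))
  expect_equal(partial$auc, 0.75)
  single <- roc_auc(c(1, 1), c(0.5, 0.6))
  expect_true(is.na(single$auc))
  # ROC polygon is monotone in both coordinates
  set.seed(9)
  r <- roc_auc(as.integer(runif(100) < 0.5), round(runif(100), 1))
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
})

test_that("trapezoidal AUC equals brute-force pairwise concordance (with ties)", {
  set.seed(10)
  for (k in 1:25) {
    n <- sample(20:300, 1)
    lab <- as.integer(runif(n) < runif(1, 0.2, 0.8))
    if (length(unique(lab)) < 2) next
    scores <- round(runif(n), sample(1:3, 1))  # coarse rounding forces ties
    expect_equal(roc_auc(lab, scores)$auc, concordance_auc(lab, scores),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(11)
  lab <- as.integer(runif(500) < 0.4)
  scores <- round(runif(500), 2)
  expect_equal(roc_auc(lab, scores)$auc,
               as.numeric(pROC::auc(pROC::roc(lab, scores, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-10)
})

test_that("random scores give chance-level AUC", {
  set.seed(12)
  lab <- as.integer(runif(1e4) < 0.5)
  expect_lt(abs(roc_auc(lab, runif(1e4))$auc - 0.5), 0.02)
})

test_that("Fmax reaches its closed-form bounds", {
  expect_equal(pr_fmax(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$fmax, 1)
  # constant score: everything called disordered at prevalence 0.25 -> F = 0.4
  const <- pr_fmax(c(1, rep(0, 3)), rep(0.7, 4))
  expect_equal(const$fmax, 0.4)
  # single positive ranked first among 10
  top <- pr_fmax(c(1, rep(0, 9)), c(0.99, runif(9, 0, 0.5)))
  expect_equal(top$fmax, 1)
  # Fmax is at least the call-everything bound 2p/(1+p), and at least any
  # single-threshold F1
  set.seed(13)
  for (k in 1:10) {
    lab <- as.integer(runif(200) < 0.3)
    if (sum(lab) == 0) next
    s <- round(runif(200), 2)
    res <- pr_fmax(lab, s)
    p <- mean(lab)
    expect_gte(res$fmax + 1e-12, 2 * p / (1 + p))
    thr <- sample(s, 1)
    cm <- confusion(lab, as.integer(s >= thr))
    f1 <- if (cm$tp == 0) 0 else {
      pr <- cm$tp / (cm$tp + cm$fp); rc <- cm$tp / (cm$tp + cm$fn)
      2 * pr * rc / (pr + rc)
    }
    expect_gte(res$fmax + 1e-12, f1)
  }
  expect_true(is.na(pr_fmax(c(0, 0), c(0.1, 0.2))$fmax))
})

test_that("residue RMSD matches its closed forms, including the random-predictor level", {
  v <- c(1, 0, 1, 0)
  expect_equal(residue_rmsd(v, v), 0)
  expect_equal(residue_rmsd(c(1, 0, 1, 0), c(0, 1, 0, 1)), 1)
  # binary vectors: sqrt(Hamming / m)
  set.seed(14)
  a <- as.integer(runif(50) < 0.5); b <- as.integer(runif(50) < 0.5)
  expect_equal(residue_rmsd(a, b), sqrt(sum(a != b) / 50))
  # masked entries are excluded from both vectors
  expect_equal(residue_rmsd(c(1, 1, 0), c(1, 0, 0), mask = c(FALSE, TRUE, FALSE)), 0)
  expect_true(is.na(residue_rmsd(c(1), c(1), mask = TRUE)))
  # two independent fair coins at m = 1e4: the ~0.707 random-predictor level
  x <- as.integer(runif(1e4) < 0.5); y <- as.integer(runif(1e4) < 0.5)
  expect_lt(abs(residue_rmsd(x, y) - sqrt(0.5)), 0.01)
})

test_that("disorder content and protein classes follow the stated cutoffs", {
  expect_equal(disorder_content(c(0, 0, 1, 1, 1, 1, 0, 0, 0, 0)), 0.4)
  expect_equal(disorder_content(c(rep(0L, 9), 1L), mask = c(rep(TRUE, 9), FALSE)), 1)
  expect_equal(protein_class(0.95), "highly_disordered")
  expect_equal(protein_class(0.05), "highly_ordered")
  expect_equal(protein_class(0.90), "other")  # boundary is strict
  expect_equal(protein_class(0.10), "other")
  expect_equal(protein_class(0.96, high = 0.95), "highly_disordered")
})

test_that("cohort disorder content matches the generator fraction", {
  cfg <- generator_config(n_proteins = 200, length_range = c(60, 120),
                          disorder_fraction = 0.3, seed = 21)
  cohort <- generate_cohort(cfg, predictor_aucs = NULL)
  contents <- vapply(cohort$labels, disorder_content, numeric(1))
  se <- sd(contents) / sqrt(length(contents))
  expect_lt(abs(mean(contents) - 0.3), 3 * se + 1e-9)
})

test_that("content histograms integrate to one and respect the bin width", {
  set.seed(22)
  contents <- runif(300)
  h <- disorder_content_histogram(contents, bin_width = 0.05)
  expect_equal(sum(h$count), 300)
  expect_equal(sum(h$density) * 0.05, 1, tolerance = 1e-12)
  coarse <- disorder_content_histogram(contents, bin_width = 0.5)
  expect_lte(nrow(coarse), 3)
})

test_that("bootstrap summaries are reproducible and correctly scaled", {
  expect_equal(bootstrap_summary(rep(3.5, 10), 100, 10, seed = 1)$stderr, 0)
  expect_equal(bootstrap_summary(rep(3.5, 10), 100, 10, seed = 1)$mean, 3.5)
  expect_error(bootstrap_summary(numeric(0)), "no values")
  set.seed(15)
  vals <- rnorm(5000)
  s <- bootstrap_summary(vals, n_samples = 4000, sample_size = 60, seed = 7)
  expect_lt(abs(s$stderr - 1 / sqrt(60)), 0.2 / sqrt(60))
  s2 <- bootstrap_summary(vals, n_samples = 4000, sample_size = 60, seed = 7)
  expect_identical(s, s2)
})

test_that("predictor correlation recovers exact linear relations", {
  x <- runif(20)
  tab <- data.frame(a = x, b = x, c = 1 - x)
  res <- predictor_correlation(tab)
  expect_equal(res$r[res$a == "a" & res$b == "b"], 1)
  expect_equal(res$r[res$a == "a" & res$b == "c"], -1)
  noisy <- data.frame(x = x, y = 2 * x + rnorm(20, sd = 1e-8))
  fit <- predictor_correlation(noisy)
  expect_equal(fit$slope, 2, tolerance = 1e-4)
  short <- data.frame(a = c(1, 2, NA), b = c(1, NA, 3))
  expect_true(is.na(predictor_correlation(short)$r))
})
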