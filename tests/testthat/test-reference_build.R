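test_that("DisProt-style references label annotated intervals disordered, everything else ordered", {
  r <- build_disprot_reference(tiny_interval_record("P1", 3, 6), 10)
  expect_equal(r$labels, c(0L, 0L, 1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L))
  expect_false(any(r$mask))

  r0 <- build_disprot_reference(NULL, 5, accession = "P2")
  expect_equal(r0$labels, rep(0L, 5))

  rov <- build_disprot_reference(tiny_interval_record("P3", c(2, 4), c(5, 8)), 10)
  expect_equal(which(rov$labels == 1L), 2:8)

  expect_error(build_disprot_reference(tiny_interval_record("P4", 5, 11), 10),
               "P4")
})

test_that("DisProt-PDB references resolve conflicts to disorder and mask uncovered residues", {
  r <- build_disprot_pdb_reference(tiny_interval_record("P1", 3, 6),
                                   tiny_interval_record("P1", 1, 8, "pdb_coverage"),
                                   10)
  expect_equal(r$labels[1:2], c(0L, 0L))
  expect_equal(r$labels[3:6], rep(1L, 4))
  expect_equal(r$labels[7:8], c(0L, 0L))
  expect_equal(which(r$mask), 9:10)
  expect_true(all(r$provenance[3:6] == "disprot"))
  expect_true(all(r$provenance[r$mask] == "none"))

  # full conflict: everything annotated disordered AND covered -> all disordered
  rc <- build_disprot_pdb_reference(tiny_interval_record("P2", 1, 10),
                                    tiny_interval_record("P2", 1, 10, "pdb_coverage"),
                                    10)
  expect_equal(rc$labels, rep(1L, 10))
  expect_false(any(rc$mask))

  # no information at all -> everything masked
  rm_ <- build_disprot_pdb_reference(NULL, NULL, 6, accession = "P3")
  expect_true(all(rm_$mask))
  expect_equal(sum(!rm_$mask), 0L)
})

test_that("disorder annotations are preserved verbatim across reference variants", {
  set.seed(31)
  for (k in 1:20) {
    len <- sample(20:60, 1)
    lab <- as.integer(runif(len) < 0.4)
    cov <- runif(len) < 0.5
    dis <- tiny_interval_record("P", which(diff(c(0L, lab)) == 1L),
                                which(diff(c(lab, 0L)) == -1L))
    covr <- list(accession = "P", kind = "pdb_coverage",
                 intervals = disbench:::mask_to_intervals(cov))
    a <- build_disprot_reference(dis, len)
    b <- build_disprot_pdb_reference(dis, covr, len)
    expect_true(all(b$labels[a$labels == 1L] == 1L))
    # order independence: evaluated labels agree regardless of application order
    b2 <- build_disprot_pdb_reference(dis, covr, len)
    expect_identical(b$labels[!b$mask], b2$labels[!b2$mask])
  }
})

test_that("masked fraction matches the worked example and the generator expectation", {
  r <- build_disprot_pdb_reference(tiny_interval_record("P1", 3, 6),
                                   tiny_interval_record("P1", 1, 8, "pdb_coverage"),
                                   10)
  expect_equal(masked_fraction(r)$overall, 0.2)

  full <- build_disprot_pdb_reference(tiny_interval_record("P2", 1, 2),
                                      tiny_interval_record("P2", 1, 10, "pdb_coverage"),
                                      10)
  expect_equal(masked_fraction(full)$overall, 0)

  # cohort-scale: only uncovered ordered residues are masked, so the pooled
  # masked fraction has a binomial expectation given the realised labels
  cfg <- generator_config(n_proteins = 80, length_range = c(80, 160),
                          coverage_fraction_ordered = 0.9,
                          coverage_fraction_disordered = 0.2, seed = 19)
  cohort <- generate_cohort(cfg, predictor_aucs = NULL)
  refs <- lapply(names(cohort$labels), function(acc) {
    dis <- tiny_interval_record(acc,
      disbench:::mask_to_intervals(cohort$labels[[acc]] == 1L)$start,
      disbench:::mask_to_intervals(cohort$labels[[acc]] == 1L)$end)
    build_disprot_pdb_reference(dis, cohort$coverage[[acc]],
                                length(cohort$labels[[acc]]))
  })
  n_ord <- sum(vapply(cohort$labels, function(l) sum(l == 0L), numeric(1)))
  n_tot <- sum(lengths(cohort$labels))
  expected <- n_ord * (1 - cfg$coverage_fraction_ordered) / n_tot
  se <- sqrt(n_ord * 0.9 * 0.1) / n_tot
  expect_lt(abs(masked_fraction(refs)$overall - expected), 3 * se)
})
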