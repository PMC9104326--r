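test_that("amide hydrogens sit 1 A from N along the previous carbonyl direction", {
  # two-residue toy geometry with a hand-computable H position
  ch <- list(resno = 1:2, resid = c("ALA", "ALA"), plddt = c(50, 50),
             N = rbind(c(-1.3, 0.5, 0), c(1.33, 0, 0)),
             CA = rbind(c(-0.8, -0.9, 0), c(2.5, 0.8, 0)),
             C = rbind(c(0, 0, 0), c(3.9, 0.2, 0)),
             O = rbind(c(0, 0, 1.23), c(4.4, 1.1, 0.5)))
  model <- place_amide_hydrogens(structure_model(list(A = ch)))
  expect_equal(model$chains$A$H[2, ], c(1.33, 0, -1.0), tolerance = 1e-12)
  expect_true(anyNA(model$chains$A$H[1, ]))  # chain start has no donor H
})

test_that("prolines receive no amide hydrogen", {
  model <- generate_backbone("HHHH", plddt = rep(60, 4))
  model$chains$A$resid[3] <- "PRO"
  model <- place_amide_hydrogens(model)
  expect_true(anyNA(model$chains$A$H[3, ]))
  expect_false(anyNA(model$chains$A$H[2, ]))
})

test_that("hydrogen-bond energy matches the electrostatic formula", {
  # geometry with r_ON = 3.0, r_CH = 3.9, r_OH = 2.0, r_CN = 4.0
  o <- c(0, 0, 0)
  n <- c(3, 0, 0)
  h <- c(2, 0, 0)          # r_OH = 2
  # place C so that |C - H| = 3.9 and |C - N| = 4.0
  # C = (x, y, 0): (x-2)^2 + y^2 = 3.9^2 ; (x-3)^2 + y^2 = 4^2
  x <- (3.9^2 - 4^2 + 9 - 4) / 2
  y <- sqrt(3.9^2 - (x - 2)^2)
  c_at <- c(x, y, 0)
  e <- hbond_energy(n, h, c_at, o)
  expect_equal(e, 27.888 * (1 / 3 + 1 / 3.9 - 1 / 2 - 1 / 4), tolerance = 1e-9)
  expect_equal(e, -4.4692, tolerance = 1e-3)
})

test_that("equidistant dipoles give zero energy and weak contacts are not bonds", {
  # regular tetrahedron: all four donor/acceptor distances equal, terms cancel
  n <- c(1, 1, 1); h <- c(1, -1, -1); c_at <- c(-1, 1, -1); o <- c(-1, -1, 1)
  expect_equal(hbond_energy(n, h, c_at, o), 0, tolerance = 1e-12)
  # near-coincident atoms are clamped, with a warning
  expect_warning(hbond_energy(c(0, 0, 0), c(0.1, 0, 0), c(0.2, 0, 0),
                              c(0.3, 0, 0)), "clamp")
})

test_that("hydrogen-bond energy is invariant under rigid motion", {
  set.seed(71)
  n <- c(1.33, 0, 0); h <- c(1.33, 0, -1); c_at <- c(0, 0, 0); o <- c(0, 0, 1.23)
  e0 <- hbond_energy(n, h, c_at, o)
  for (k in 1:10) {
    R <- random_rotation()
    t <- rnorm(3, sd = 10)
    expect_equal(hbond_energy(R %*% n + t, R %*% h + t, R %*% c_at + t,
                              R %*% o + t), e0, tolerance = 1e-9)
  }
})

test_that("ideal helices and paired strands recover H and E, matching the reference implementation", {
  helix <- generate_backbone(strrep("H", 12))
  ss_h <- assign_ss8(helix)[["A"]]
  expect_equal(substr(ss_h, 2, 11), strrep("H", 10))

  pair <- generate_backbone(list(kind = "strand_pair", length = 8))
  ss_p <- assign_ss8(pair)
  expect_equal(substr(ss_p[["A"]], 2, 7), strrep("E", 6))
  expect_equal(substr(ss_p[["B"]], 2, 7), strrep("E", 6))

  dir <- withr::local_tempdir()
  ph <- file.path(dir, "helix.pdb"); pp <- file.path(dir, "pair.pdb")
  write_structure(helix, ph)
  write_structure(pair, pp)
  oracle <- reference_dssp(c(ph, pp))
  expect_equal(ss_h, oracle[1])
  expect_equal(paste(ss_p, collapse = ""), oracle[2])
})

test_that("an isolated extended strand has no E (bridges need a partner)", {
  lone <- generate_backbone(strrep("E", 10))
  expect_false(grepl("E", assign_ss8(lone)[["A"]]))
})

test_that("assignment is deterministic and short chains fall back to coil", {
  model <- generate_backbone(paste0("CC", strrep("H", 9), "CC"), seed = 5)
  expect_identical(assign_ss8(model), assign_ss8(model))
  short <- generate_backbone("HHHH", plddt = rep(70, 4))
  expect_warning(ss <- assign_ss8(short), "shorter than 5")
  expect_equal(ss[["A"]], "----")
})

test_that("the 8-to-4-class reduction maps every class and keeps length", {
  expect_equal(unname(reduce_ss("HGIEBTS-")), "HHHEETCC")
  expect_equal(unname(reduce_ss("")), "")
  expect_equal(unname(reduce_ss("--------")), "CCCCCCCC")
  expect_error(reduce_ss("HX"), "unknown")
})

test_that("the classic DSSP table reader recovers per-chain strings", {
  path <- withr::local_tempfile(fileext = ".dssp")
  writeLines(c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    "    1    1 A A  H  >S+",
    "    2    2 A A  H  3S+",
    "    3    3 A A  T  <",
    "    4    4 A A     ",
    "    5    1 B A  E  b"), path)
  ss <- read_dssp_file(path)
  expect_equal(ss[["A"]], "HHT-")
  expect_equal(ss[["B"]], "E")
})
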