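# Synthetic cohort generator: two-state (ordered/disordered) proteins with
# confidence profiles, secondary-structure strings, ideal backbone
# coordinates, partial structural coverage, and emulated external-predictor
# scores. The generator is the ground truth every pipeline stage is tested
# against; its statistical structure (Markov segments, binormal confidence,
# transient-helix / confident-coil discordance knobs) is documented in the
# methods vignette.

# ideal backbone internal coordinates (Angstrom / degrees)
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
BOND_C_O <- 1.231
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7
ANGLE_CA_C_O <- 120.8
TORSION_HELIX <- c(phi = -57, psi = -47)
TORSION_STRAND <- c(phi = -139, psi = 135)

#' Generator configuration
#'
#' Bundles every knob of the synthetic cohort generator. Defaults describe a
#' disorder-enriched benchmark cohort: segmental disorder at 35% of
#' residues, confidently ordered regions around pLDDT 85 and disordered
#' regions around 45, structural (PDB-style) coverage biased toward ordered
#' regions, and the two discordance knobs — `transient_helix_rate` (fraction
#' of disordered residues that nonetheless look helical) and
#' `confident_coil_rate` (fraction of ordered residues that look coiled) —
#' that make the secondary-structure rule and the confidence rule disagree.
#'
#' @param n_proteins number of proteins in the cohort.
#' @param length_range integer (min, max) protein length.
#' @param disorder_fraction stationary fraction of disordered residues.
#' @param mean_segment_length mean disordered-segment length, residues
#'   (ordered segments get `mean * (1-d)/d` so the stationary fraction is
#'   exactly `disorder_fraction`).
#' @param plddt_ordered,plddt_disordered numeric (mean, sd) of the
#'   confidence score per state, pLDDT units.
#' @param smoothing_window centred moving-average window (residues) applied
#'   to confidence profiles; 1 disables smoothing.
#' @param coverage_fraction_ordered,coverage_fraction_disordered per-residue
#'   probability of structural coverage by state.
#' @param transient_helix_rate,confident_coil_rate discordance knobs in
#'   \[0, 1\].
#' @param seed integer; fully determines the cohort.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_proteins = 200L,
                             length_range = c(80L, 300L),
                             disorder_fraction = 0.35,
                             mean_segment_length = 30,
                             plddt_ordered = c(85, 8),
                             plddt_disordered = c(45, 12),
                             smoothing_window = 5L,
                             coverage_fraction_ordered = 0.9,
                             coverage_fraction_disordered = 0.2,
                             transient_helix_rate = 0.2,
                             confident_coil_rate = 0.1,
                             seed = 1L) {
  # tolerate list-valued pairs (as round-tripped through JSON/YAML manifests)
  length_range <- unlist(length_range)
  plddt_ordered <- unlist(plddt_ordered)
  plddt_disordered <- unlist(plddt_disordered)
  cfg <- list(n_proteins = as.integer(n_proteins),
              length_range = as.integer(length_range),
              disorder_fraction = disorder_fraction,
              mean_segment_length = mean_segment_length,
              plddt_ordered = plddt_ordered,
              plddt_disordered = plddt_disordered,
              smoothing_window = as.integer(smoothing_window),
              coverage_fraction_ordered = coverage_fraction_ordered,
              coverage_fraction_disordered = coverage_fraction_disordered,
              transient_helix_rate = transient_helix_rate,
              confident_coil_rate = confident_coil_rate,
              seed = as.integer(seed))
  fr <- c(cfg$disorder_fraction, cfg$coverage_fraction_ordered,
          cfg$coverage_fraction_disordered, cfg$transient_helix_rate,
          cfg$confident_coil_rate)
  stopifnot(all(fr >= 0 & fr <= 1),
            cfg$plddt_ordered[1] >= 0, cfg$plddt_ordered[1] <= 100,
            cfg$plddt_disordered[1] >= 0, cfg$plddt_disordered[1] <= 100,
            length(cfg$length_range) == 2L,
            cfg$length_range[1] >= 5L,
            cfg$length_range[1] <= cfg$length_range[2])
  class(cfg) <- "generator_config"
  cfg
}

#' Generate per-protein disorder label strings
#'
#' Two-state Markov segment process: geometric segment lengths with mean
#' `mean_segment_length` for disordered runs and `mean * (1-d)/d` for
#' ordered runs, so the stationary disordered fraction equals
#' `disorder_fraction`. Draws from the current RNG stream; wrap in a seed
#' for reproducibility (as [generate_cohort()] does).
#'
#' @param config a [generator_config()].
#' @return Named list of integer vectors (0 ordered / 1 disordered).
#' @export
generate_labels <- function(config) {
  d <- config$disorder_fraction
  if (config$mean_segment_length < 2) {
    stop("mean_segment_length must be at least 2 residues")
  }
  lens <- sample(config$length_range[1]:config$length_range[2],
                 config$n_proteins, replace = TRUE)
  labs <- vector("list", config$n_proteins)
  names(labs) <- sprintf("SYN%04d", seq_len(config$n_proteins))
  for (p in seq_len(config$n_proteins)) {
    n <- lens[p]
    if (d == 0) { labs[[p]] <- integer(n); next }
    if (d == 1) { labs[[p]] <- rep(1L, n); next }
    l_dis <- config$mean_segment_length
    l_ord <- l_dis * (1 - d) / d
    p_exit <- c(min(1, 1 / l_ord), min(1, 1 / l_dis))  # by state 0 / 1
    state <- as.integer(runif(1) < d)
    v <- integer(n)
    for (i in seq_len(n)) {
      v[i] <- state
      if (runif(1) < p_exit[state + 1L]) state <- 1L - state
    }
    labs[[p]] <- v
  }
  labs
}

#' Generate per-residue confidence profiles
#'
#' Ordered residues draw from `Normal(plddt_ordered)`, disordered from
#' `Normal(plddt_disordered)`, truncated (clamped) to \[0, 100\], then
#' smoothed with a centred moving average of `smoothing_window` residues.
#' For the unsmoothed process with a common sd, the tpLD score separates
#' the states with a theoretical AUC of `pnorm(dprime / sqrt(2))` where
#' `dprime = (mu_ordered - mu_disordered) / sd`.
#'
#' @param labels list from [generate_labels()].
#' @param config a [generator_config()].
#' @return Named list of numeric pLDDT vectors in \[0, 100\].
#' @export
generate_plddt <- function(labels, config) {
  mu <- c(config$plddt_ordered[1], config$plddt_disordered[1])
  sdv <- c(config$plddt_ordered[2], config$plddt_disordered[2])
  lapply(labels, function(lab) {
    x <- rnorm(length(lab), mean = mu[lab + 1L], sd = sdv[lab + 1L])
    x <- pmin(100, pmax(0, x))
    moving_average(x, config$smoothing_window)
  })
}

# fill an ordered segment with helix/strand elements separated by turn caps
fill_ordered_segment <- function(m) {
  out <- character(0)
  while (length(out) < m) {
    if (length(out) > 0L) out <- c(out, rep("T", min(2L, m - length(out))))
    if (length(out) >= m) break
    room <- m - length(out)
    if (runif(1) < 0.65) {
      len <- min(room, sample(6:14, 1))
      out <- c(out, rep("H", len))
    } else {
      len <- min(room, sample(4:8, 1))
      out <- c(out, rep("E", len))
    }
  }
  out[seq_len(m)]
}

#' Generate secondary-structure strings consistent with disorder labels
#'
#' Ordered segments are filled with helix and strand elements separated by
#' hydrogen-bonded turn caps (all classes the naive structure rule counts
#' as ordered); disordered segments are coil/bend. Two knobs then inject
#' the discordance observed in real predicted structures: a
#' `transient_helix_rate` fraction of each disordered segment becomes a
#' (low-confidence) helix, and each ordered residue independently becomes
#' coil with probability `confident_coil_rate`. With both rates zero the
#' naive structure rule reproduces the labels exactly.
#'
#' @param labels list from [generate_labels()].
#' @param config a [generator_config()].
#' @return Named list; per protein a list with `ss8` and `reduced` strings.
#' @export
generate_ss <- function(labels, config) {
  out <- lapply(labels, function(lab) {
    n <- length(lab)
    chars <- character(n)
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      idx <- starts[k]:ends[k]
      m <- length(idx)
      if (r$values[k] == 0L) {
        chars[idx] <- fill_ordered_segment(m)
      } else {
        chars[idx] <- ifelse(runif(m) < 0.3, "S", "-")
        th <- round(config$transient_helix_rate * m)
        if (th >= 4L) {
          at <- sample.int(m - th + 1L, 1)
          chars[idx[at:(at + th - 1L)]] <- "H"
        }
      }
    }
    flip <- lab == 0L & runif(n) < config$confident_coil_rate
    chars[flip] <- ifelse(runif(sum(flip)) < 0.3, "S", "-")
    ss8 <- paste(chars, collapse = "")
    list(ss8 = ss8, reduced = unname(reduce_ss(ss8)))
  })
  names(out) <- names(labels)
  out
}

# --- backbone construction -------------------------------------------------

dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / vec_norm(b2)
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Natural-extension placement: position D with |C-D| = bond,
# angle(B,C,D) = angle_deg and dihedral(A,B,C,D) = torsion_deg.
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  th <- angle_deg * pi / 180
  chi <- torsion_deg * pi / 180
  d2 <- bond * c(-cos(th), sin(th) * cos(chi), sin(th) * sin(chi))
  bc <- unit_vec(c - b)
  nv <- unit_vec(crossp(b - a, bc))
  mv <- crossp(nv, bc)
  c + bc * d2[1] + mv * d2[2] + nv * d2[3]
}

crossp <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

sample_coil_torsions <- function(n) {
  region <- sample.int(3L, n, replace = TRUE, prob = c(0.5, 0.25, 0.25))
  phi <- numeric(n); psi <- numeric(n)
  for (i in seq_len(n)) {
    if (region[i] == 1L) {        # broad beta basin
      phi[i] <- runif(1, -160, -70); psi[i] <- runif(1, 100, 175)
    } else if (region[i] == 2L) { # polyproline-II-like
      phi[i] <- runif(1, -90, -55); psi[i] <- runif(1, 130, 170)
    } else {                      # right-handed alpha basin
      phi[i] <- runif(1, -90, -45); psi[i] <- runif(1, -50, -10)
    }
  }
  cbind(phi = phi, psi = psi)
}

# build one chain from per-residue (phi, psi); returns list of coordinate
# matrices N, CA, C, O
build_chain_from_torsions <- function(torsions) {
  n <- nrow(torsions)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BOND_N_CA, 0, 0)
  th <- ANGLE_N_CA_C * pi / 180
  C[1, ] <- CA[1, ] + BOND_CA_C * c(-cos(th), sin(th), 0)
  for (i in 2:n) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         BOND_C_N, ANGLE_CA_C_N, torsions[i - 1, "psi"])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          BOND_N_CA, ANGLE_C_N_CA, 180)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                         BOND_CA_C, ANGLE_N_CA_C, torsions[i, "phi"])
  }
  for (i in seq_len(n)) {
    psi <- if (i < n) torsions[i, "psi"] else 140
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         BOND_C_O, ANGLE_CA_C_O, psi - 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

chain_to_model_chain <- function(xyz, plddt = NULL) {
  n <- nrow(xyz$N)
  if (is.null(plddt)) plddt <- rep(70, n)
  list(resno = seq_len(n), resid = rep("ALA", n), plddt = plddt,
       N = xyz$N, CA = xyz$CA, C = xyz$C, O = xyz$O)
}

min_nonadjacent_ca_dist <- function(CA) {
  n <- nrow(CA)
  if (n < 3L) return(Inf)
  dmin <- Inf
  for (i in seq_len(n - 2L)) {
    d2 <- (CA[(i + 2L):n, 1] - CA[i, 1])^2 +
          (CA[(i + 2L):n, 2] - CA[i, 2])^2 +
          (CA[(i + 2L):n, 3] - CA[i, 3])^2
    dmin <- min(dmin, sqrt(min(d2)))
  }
  dmin
}

rigid_transform <- function(xyz_list, par, centre) {
  cx <- cos(par[4]); sx <- sin(par[4])
  cy <- cos(par[5]); sy <- sin(par[5])
  cz <- cos(par[6]); sz <- sin(par[6])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  R <- Rz %*% Ry %*% Rx
  lapply(xyz_list, function(M) {
    sweep(sweep(M, 2, centre) %*% t(R), 2, centre + par[1:3], `+`)
  })
}

# Place a second strand antiparallel to the first at hydrogen-bond register
# by least-squares fitting of the ideal O..N distances.
pair_strands_antiparallel <- function(xyzA, xyzB) {
  n <- nrow(xyzA$N)
  centre <- colMeans(xyzB$CA)
  partner <- function(k) n + 1L - k
  bonded <- seq(2, n - 1, by = 2)
  objective <- function(par) {
    tb <- rigid_transform(xyzB, par, centre)
    err <- 0
    for (k in bonded) {
      j <- partner(k)
      err <- err + (vec_norm(xyzA$O[k, ] - tb$N[j, ]) - 2.9)^2
      err <- err + (vec_norm(xyzA$N[k, ] - tb$O[j, ]) - 2.9)^2
    }
    for (k in seq_len(n)) {
      err <- err + 0.1 * (vec_norm(xyzA$CA[k, ] - tb$CA[partner(k), ]) - 4.9)^2
    }
    err
  }
  start <- c(0, 4.8, 0, 0, 0, pi)
  fit <- stats::optim(start, objective, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  fit2 <- stats::optim(fit$par, objective, method = "Nelder-Mead",
                       control = list(maxit = 2000))
  best <- if (fit2$value < fit$value) fit2 else fit
  rigid_transform(xyzB, best$par, centre)
}

#' Build ideal backbone coordinates for a secondary-structure specification
#'
#' Chains are grown residue by residue from ideal bond lengths and angles by
#' torsion placement: helix residues at (phi, psi) = (-57, -47), strand
#' residues at (-139, 135), and coil residues at torsions drawn uniformly
#' from allowed Ramachandran basins. A steric guard regenerates coil
#' torsions (up to 100 times) when any non-adjacent CA pair comes closer
#' than 2 Angstrom. `kind = "strand_pair"` builds two strand chains and
#' rigid-fits the second antiparallel to the first at hydrogen-bond
#' register.
#'
#' @param ss_spec either a character string over `H` (helix), `E` (strand),
#'   `C` (coil) for a single chain, or `list(kind = "strand_pair", length = n)`.
#' @param plddt optional per-residue confidence to store (default 70).
#' @param seed optional integer; when given, coil draws are reproducible.
#' @return A [structure_model()].
#' @export
generate_backbone <- function(ss_spec, plddt = NULL, seed = NULL) {
  build <- function() {
    if (is.list(ss_spec) && identical(ss_spec$kind, "strand_pair")) {
      n <- ss_spec$length
      tors <- matrix(rep(TORSION_STRAND, each = n), n,
                     dimnames = list(NULL, c("phi", "psi")))
      xyzA <- build_chain_from_torsions(tors)
      xyzB <- build_chain_from_torsions(tors)
      xyzB <- pair_strands_antiparallel(xyzA, xyzB)
      names(xyzB) <- names(xyzA)
      return(structure_model(list(A = chain_to_model_chain(xyzA, plddt),
                                  B = chain_to_model_chain(xyzB, plddt))))
    }
    chars <- strsplit(ss_spec, "")[[1]]
    stopifnot(all(chars %in% c("H", "E", "C")))
    n <- length(chars)
    for (attempt in seq_len(100L)) {
      tors <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("phi", "psi")))
      tors[chars == "H", ] <- matrix(rep(TORSION_HELIX, each = sum(chars == "H")),
                                     ncol = 2)
      tors[chars == "E", ] <- matrix(rep(TORSION_STRAND, each = sum(chars == "E")),
                                     ncol = 2)
      if (any(chars == "C")) {
        tors[chars == "C", ] <- sample_coil_torsions(sum(chars == "C"))
      }
      xyz <- build_chain_from_torsions(tors)
      if (min_nonadjacent_ca_dist(xyz$CA) >= 2 || !any(chars == "C")) {
        return(structure_model(list(A = chain_to_model_chain(xyz, plddt))))
      }
    }
    stop("failed to build a clash-free chain in 100 attempts")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Generate structural-coverage intervals
#'
#' Each residue is covered independently with probability
#' `coverage_fraction_ordered` (ordered) or `coverage_fraction_disordered`
#' (disordered); covered runs are merged into 1-based inclusive intervals,
#' emulating partial PDB coverage biased toward ordered regions.
#'
#' @param labels list from [generate_labels()].
#' @param config a [generator_config()].
#' @return Named list of annotation records (as from [read_intervals()],
#'   kind `"pdb_coverage"`).
#' @export
generate_coverage <- function(labels, config) {
  out <- lapply(names(labels), function(acc) {
    lab <- labels[[acc]]
    p <- ifelse(lab == 1L, config$coverage_fraction_disordered,
                config$coverage_fraction_ordered)
    covered <- runif(length(lab)) < p
    list(accession = acc, kind = "pdb_coverage",
         intervals = mask_to_intervals(covered))
  })
  names(out) <- names(labels)
  out
}

#' Emulate an external per-residue disorder predictor
#'
#' Scores follow a binormal model calibrated so the theoretical AUC against
#' the true labels equals `accuracy_auc`: disordered residues draw from
#' `N(sqrt(2) * qnorm(auc), 1)`, ordered from `N(0, 1)`, then a logistic
#' squash maps scores into \[0, 1\] (rank-preserving, so the AUC is
#' unchanged). Binary labels cut at the equal-error threshold.
#'
#' @param labels list from [generate_labels()].
#' @param accuracy_auc target AUC in \[0.5, 1\].
#' @param name predictor name recorded in each record.
#' @return Named list of CAID-style prediction records.
#' @export
generate_predictor_files <- function(labels, accuracy_auc, name = "emulated") {
  stopifnot(accuracy_auc >= 0.5, accuracy_auc <= 1)
  mu1 <- sqrt(2) * qnorm(min(accuracy_auc, 1 - 1e-12))
  out <- lapply(names(labels), function(acc) {
    lab <- labels[[acc]]
    z <- rnorm(length(lab), mean = ifelse(lab == 1L, mu1, 0), sd = 1)
    score <- plogis(z - mu1 / 2)
    list(accession = acc, predictor = name,
         position = seq_along(lab), residue = rep("A", length(lab)),
         score = score, label = as.integer(score >= 0.5))
  })
  names(out) <- names(labels)
  out
}

#' Generate a complete synthetic cohort
#'
#' Draws labels, confidence profiles, secondary-structure strings, coverage
#' intervals, and emulated external-predictor files under a single seed, so
#' an identical configuration reproduces the cohort exactly.
#'
#' @param config a [generator_config()].
#' @param predictor_aucs named numeric vector of target AUCs for emulated
#'   external predictors (may be empty).
#' @return A list of class `synthetic_cohort` with elements `labels`,
#'   `plddt`, `ss`, `coverage`, `predictors`, and `config`.
#' @export
generate_cohort <- function(config = generator_config(),
                            predictor_aucs = c(emulated_strong = 0.92,
                                               emulated_mid = 0.75,
                                               emulated_random = 0.5)) {
  with_seed(config$seed, {
    labels <- generate_labels(config)
    plddt <- generate_plddt(labels, config)
    ss <- generate_ss(labels, config)
    coverage <- generate_coverage(labels, config)
    predictors <- lapply(seq_along(predictor_aucs), function(k) {
      generate_predictor_files(labels, predictor_aucs[[k]],
                               name = names(predictor_aucs)[k])
    })
    names(predictors) <- names(predictor_aucs)
    structure(list(labels = labels, plddt = plddt, ss = ss,
                   coverage = coverage, predictors = predictors,
                   config = config),
              class = "synthetic_cohort")
  })
}

#' Write a synthetic cohort to disk
#'
#' Emits the disorder and coverage interval tables (TSV), one CAID-format
#' file per emulated predictor, optionally one PDB structure per protein
#' (backbone built from the secondary-structure string, confidence in the
#' B-factor column), and a JSON manifest with the generator configuration.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param structures logical; also write PDB files (slower).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir, structures = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dis <- lapply(names(cohort$labels), function(acc) {
    list(accession = acc, kind = "disorder",
         intervals = mask_to_intervals(cohort$labels[[acc]] == 1L))
  })
  names(dis) <- names(cohort$labels)
  write_intervals(dis, file.path(dir, "disorder.tsv"))
  write_intervals(cohort$coverage, file.path(dir, "coverage.tsv"))
  for (pname in names(cohort$predictors)) {
    write_caid_predictions(cohort$predictors[[pname]],
                           file.path(dir, paste0(pname, ".caid")))
  }
  if (structures) {
    sdir <- file.path(dir, "structures")
    dir.create(sdir, showWarnings = FALSE)
    for (acc in names(cohort$labels)) {
      spec <- chartr("HGIEBTS-", "HHHEECCC", cohort$ss[[acc]]$ss8)
      model <- generate_backbone(spec, plddt = cohort$plddt[[acc]],
                                 seed = cohort$config$seed + match(acc, names(cohort$labels)))
      write_structure(model, file.path(sdir, paste0(acc, ".pdb")))
    }
  }
  manifest <- cohort$config
  class(manifest) <- NULL
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
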