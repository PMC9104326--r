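# End-to-end orchestration: generate (or accept) a cohort, build both
# reference variants, derive the structure-based predictors, ingest
# emulated external predictions, and evaluate everything into one report.

#' Run configuration
#'
#' @param generator a [generator_config()].
#' @param predictor_aucs named numeric vector of emulated external
#'   predictor AUCs.
#' @param class_high,class_low disorder-content cutoffs for protein classes.
#' @param bootstrap_protein,bootstrap_residue `(n_samples, sample_size)`
#'   for protein-level and residue-level bootstraps.
#' @param content_bin_width histogram bin width for disorder-content
#'   distributions.
#' @param seed master seed; the generator seed and all bootstrap seeds
#'   derive from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       predictor_aucs = c(emulated_strong = 0.92,
                                          emulated_mid = 0.75,
                                          emulated_random = 0.5),
                       class_high = 0.90, class_low = 0.10,
                       bootstrap_protein = c(10000L, 60L),
                       bootstrap_residue = c(10000L, 500L),
                       content_bin_width = 0.05,
                       seed = 1L) {
  generator$seed <- as.integer(seed)
  structure(list(generator = generator, predictor_aucs = predictor_aucs,
                 class_high = class_high, class_low = class_low,
                 bootstrap_protein = as.integer(bootstrap_protein),
                 bootstrap_residue = as.integer(bootstrap_residue),
                 content_bin_width = content_bin_width,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the [run_config()] and
#' [generator_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen_args <- y$generator
  gen <- if (is.null(gen_args)) generator_config()
         else do.call(generator_config, gen_args)
  args <- y[setdiff(names(y), "generator")]
  if (!is.null(args$predictor_aucs)) {
    args$predictor_aucs <- unlist(args$predictor_aucs)
  }
  do.call(run_config, c(list(generator = gen), args))
}

# build both reference variants from cohort truth
cohort_references <- function(cohort) {
  accs <- names(cohort$labels)
  disprot <- list(); disprot_pdb <- list()
  for (acc in accs) {
    lab <- cohort$labels[[acc]]
    dis <- list(accession = acc, kind = "disorder",
                intervals = mask_to_intervals(lab == 1L))
    disprot[[acc]] <- build_disprot_reference(dis, length(lab))
    disprot_pdb[[acc]] <- build_disprot_pdb_reference(
      dis, cohort$coverage[[acc]], length(lab))
  }
  list(disprot = disprot, disprot_pdb = disprot_pdb)
}

reference_fingerprint <- function(references) {
  c(n_proteins = length(references),
    n_residues = sum(vapply(references, function(r) length(r$labels), numeric(1))),
    n_disordered = sum(vapply(references, function(r)
      sum(r$labels == 1L & !r$mask), numeric(1))),
    n_masked = sum(vapply(references, function(r) sum(r$mask), numeric(1))))
}

pool_residues <- function(references, per_protein) {
  accs <- names(references)
  list(labels = unlist(lapply(accs, function(a) references[[a]]$labels),
                       use.names = FALSE),
       values = unlist(lapply(accs, function(a) per_protein[[a]]),
                       use.names = FALSE),
       mask = unlist(lapply(accs, function(a) references[[a]]$mask),
                     use.names = FALSE))
}

# evaluate one predictor (scores and/or calls, per accession) on a reference
evaluate_predictor <- function(name, references, scores = NULL, calls = NULL,
                               config) {
  accs <- names(references)
  pooled_s <- if (!is.null(scores)) pool_residues(references, scores)
  pooled_c <- if (!is.null(calls)) pool_residues(references, calls)
  auc <- if (!is.null(scores)) {
    roc_auc(pooled_s$labels, pooled_s$values, pooled_s$mask)$auc
  } else NA_real_
  fmax <- if (!is.null(scores)) {
    pr_fmax(pooled_s$labels, pooled_s$values, pooled_s$mask)$fmax
  } else NA_real_
  mcc_val <- if (!is.null(calls)) {
    mcc(confusion(pooled_c$labels, pooled_c$values, pooled_c$mask))
  } else NA_real_
  vecs <- if (!is.null(calls)) calls else scores
  rmsd <- vapply(accs, function(a) {
    residue_rmsd(references[[a]]$labels, vecs[[a]], references[[a]]$mask)
  }, numeric(1))
  content <- vapply(accs, function(a) {
    r <- references[[a]]
    if (all(r$mask)) NA_real_ else disorder_content(vecs[[a]], r$mask)
  }, numeric(1))
  list(predictor = name, auc = auc, fmax = fmax, mcc = mcc_val,
       rmsd_per_protein = rmsd, content_per_protein = content)
}

#' Evaluate a set of predictors against one reference set
#'
#' Pools evaluated residues for the threshold-free metrics (AUC, Fmax,
#' MCC), computes per-protein RMSD with a protein-level bootstrap and a
#' per-class breakdown, and collects disorder-content distributions.
#' Proteins with no evaluated residues are dropped with a warning.
#'
#' @param references named list of `reference_labels`.
#' @param predictions list of predictor entries, each
#'   `list(name, scores = NULL, calls = NULL)` holding named per-accession
#'   vectors.
#' @param dataset label for the report.
#' @param config a [run_config()] (bootstrap sizes, class cutoffs, seed).
#' @return A list of class `evaluation_report`.
#' @export
evaluate_report <- function(references, predictions, dataset, config) {
  empty <- vapply(references, function(r) all(r$mask), logical(1))
  if (any(empty)) {
    warning(sum(empty), " protein(s) with no evaluated residues dropped from ",
            dataset)
    references <- references[!empty]
  }
  accs <- names(references)
  ref_content <- vapply(accs, function(a) {
    disorder_content(references[[a]]$labels, references[[a]]$mask)
  }, numeric(1))
  classes <- vapply(ref_content, protein_class, character(1),
                    high = config$class_high, low = config$class_low)
  rows <- list(); rmsd_tab <- list(); boot <- list(); by_class <- list()
  content <- list(reference = ref_content)
  for (p in predictions) {
    ev <- evaluate_predictor(p$name, references, p$scores, p$calls, config)
    b <- bootstrap_summary(ev$rmsd_per_protein[is.finite(ev$rmsd_per_protein)],
                           n_samples = config$bootstrap_protein[1],
                           sample_size = config$bootstrap_protein[2],
                           seed = config$seed)
    rows[[p$name]] <- data.frame(
      predictor = p$name, auc = ev$auc, fmax = ev$fmax, mcc = ev$mcc,
      mean_rmsd = mean(ev$rmsd_per_protein, na.rm = TRUE),
      rmsd_boot_mean = b$mean, rmsd_boot_stderr = b$stderr)
    rmsd_tab[[p$name]] <- ev$rmsd_per_protein
    boot[[p$name]] <- b
    content[[p$name]] <- ev$content_per_protein
    by_class[[p$name]] <- vapply(split(ev$rmsd_per_protein, classes),
                                 mean, numeric(1), na.rm = TRUE)
  }
  structure(list(dataset = dataset,
                 metrics = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 rmsd_per_protein = as.data.frame(rmsd_tab),
                 rmsd_by_class = by_class,
                 bootstrap = boot,
                 content = content,
                 protein_classes = classes,
                 fingerprint = reference_fingerprint(references)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s (%d proteins, %d evaluated residues)\n",
              x$dataset, x$fingerprint[["n_proteins"]],
              x$fingerprint[["n_residues"]] - x$fingerprint[["n_masked"]]))
  print(x$metrics, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Run the full synthetic benchmark
#'
#' Generates a cohort, builds the DisProt-style and DisProt-PDB-style
#' references, derives the three structure-based predictors (tpLD from the
#' confidence profile, pLDn at the MCC-optimal threshold of each dataset
#' plus their combined threshold, and the naive structure rule DSSPp from
#' the secondary-structure strings), adds the emulated external predictors,
#' and evaluates everything on both datasets.
#'
#' @param config a [run_config()].
#' @return A list of class `benchmark_run`: `cohort`, `thresholds`
#'   (per-dataset searches and the combined value), `reports` (one
#'   `evaluation_report` per dataset), `ssc` (per-class confidence
#'   distributions), and `manifest`.
#' @export
run_benchmark <- function(config = run_config()) {
  cohort <- generate_cohort(config$generator, config$predictor_aucs)
  if (length(cohort$labels) == 0L) stop("empty protein set")
  refs <- cohort_references(cohort)

  ts_disprot <- select_threshold_mcc(cohort$plddt, refs$disprot,
                                     dataset = "disprot")
  ts_pdb <- select_threshold_mcc(cohort$plddt, refs$disprot_pdb,
                                 dataset = "disprot_pdb")
  n_comb <- combine_thresholds(c(ts_disprot$best_n, ts_pdb$best_n))

  tpld_scores <- lapply(cohort$plddt, tpld_predict)
  dsspp_calls <- lapply(cohort$ss, function(s) dsspp_predict(s$ss8))
  preds_for <- function(best_n) {
    pldn_name <- sprintf("pLD%d", best_n)
    comb_name <- sprintf("pLD%d_combined", n_comb)
    out <- list(
      list(name = "tpLD", scores = tpld_scores, calls = NULL),
      list(name = pldn_name, scores = NULL,
           calls = lapply(cohort$plddt, pldn_predict, n = best_n)),
      list(name = comb_name, scores = NULL,
           calls = lapply(cohort$plddt, pldn_predict, n = n_comb)),
      list(name = "DSSPp", scores = NULL, calls = dsspp_calls))
    for (pname in names(cohort$predictors)) {
      pr <- cohort$predictors[[pname]]
      out[[length(out) + 1L]] <- list(
        name = pname,
        scores = lapply(pr, `[[`, "score"),
        calls = lapply(pr, `[[`, "label"))
    }
    out
  }
  reports <- list(
    disprot = evaluate_report(refs$disprot, preds_for(ts_disprot$best_n),
                              "disprot", config),
    disprot_pdb = evaluate_report(refs$disprot_pdb, preds_for(ts_pdb$best_n),
                                  "disprot_pdb", config))

  reduced_all <- vapply(cohort$ss, `[[`, character(1), "reduced")
  plddt_all <- unlist(cohort$plddt[names(reduced_all)], use.names = FALSE)
  ssc <- plddt_by_class(paste(reduced_all, collapse = ""), plddt_all,
                        bootstrap_seed = config$seed)

  manifest <- list(package_version = as.character(utils::packageVersion("disbench")),
                   seed = config$seed,
                   generator = unclass(config$generator),
                   predictor_aucs = as.list(config$predictor_aucs),
                   class_cutoffs = c(high = config$class_high,
                                     low = config$class_low),
                   bootstrap = list(protein = config$bootstrap_protein,
                                    residue = config$bootstrap_residue),
                   masked_fraction_disprot_pdb =
                     masked_fraction(refs$disprot_pdb)$overall)
  structure(list(cohort = cohort,
                 references = refs,
                 thresholds = list(disprot = ts_disprot, disprot_pdb = ts_pdb,
                                   combined = n_comb),
                 reports = reports, ssc = ssc, manifest = manifest),
            class = "benchmark_run")
}

#' @export
print.benchmark_run <- function(x, ...) {
  cat("<benchmark_run>\n")
  cat(sprintf("  thresholds: %d (disprot), %d (disprot_pdb), combined %d\n",
              x$thresholds$disprot$best_n, x$thresholds$disprot_pdb$best_n,
              x$thresholds$combined))
  for (r in x$reports) print(r)
  invisible(x)
}

#' Cross-predictor comparison table
#'
#' Merges evaluation reports computed on the same reference set into a
#' table sorted by each metric, plus the pairwise per-protein RMSD
#' correlation matrix. Reports with different reference fingerprints are
#' refused.
#'
#' @param reports list of `evaluation_report` objects on one reference.
#' @return List with `table` (metrics, one row per predictor, sorted by
#'   AUC), `order_by` (predictor rankings per metric), and `correlations`
#'   (from [predictor_correlation()]).
#' @export
compare_reports <- function(reports) {
  stopifnot(length(reports) >= 1L)
  fps <- lapply(reports, `[[`, "fingerprint")
  if (!all(vapply(fps, identical, logical(1), fps[[1]]))) {
    stop("reports computed on different references cannot be compared")
  }
  tab <- do.call(rbind, lapply(reports, `[[`, "metrics"))
  tab <- tab[!duplicated(tab$predictor), , drop = FALSE]
  rmsd <- do.call(cbind, lapply(reports, `[[`, "rmsd_per_protein"))
  rmsd <- rmsd[, !duplicated(names(rmsd)), drop = FALSE]
  order_by <- list(
    auc = tab$predictor[order(-tab$auc)],
    fmax = tab$predictor[order(-tab$fmax)],
    mcc = tab$predictor[order(-tab$mcc)],
    mean_rmsd = tab$predictor[order(tab$mean_rmsd)])
  list(table = tab[order(-tab$auc), , drop = FALSE],
       order_by = order_by,
       correlations = if (ncol(rmsd) >= 2L) predictor_correlation(rmsd) else NULL)
}

#' Write a benchmark report to disk
#'
#' Emits the metrics tables as TSV, the manifest and threshold search as
#' JSON, and the pooled per-residue call table.
#'
#' @param run a `benchmark_run`.
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
write_benchmark_report <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ds in names(run$reports)) {
    write.table(run$reports[[ds]]$metrics,
                file.path(dir, paste0("metrics_", ds, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(cbind(accession = rownames(run$reports[[ds]]$rmsd_per_protein),
                      run$reports[[ds]]$rmsd_per_protein),
                file.path(dir, paste0("rmsd_", ds, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(manifest = run$manifest,
         thresholds = list(disprot = run$thresholds$disprot$best_n,
                           disprot_pdb = run$thresholds$disprot_pdb$best_n,
                           combined = run$thresholds$combined)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
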