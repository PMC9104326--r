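# Reference label construction: the DisProt-style set (everything not
# annotated as disordered counts as ordered) and the DisProt-PDB-style set
# (only residues with a disorder annotation or structural coverage are
# evaluated; annotation-vs-structure conflicts resolve to disorder; the
# rest is masked).

new_reference_labels <- function(accession, labels, mask, provenance) {
  structure(list(accession = accession, labels = as.integer(labels),
                 mask = mask, provenance = provenance),
            class = "reference_labels")
}

#' @export
print.reference_labels <- function(x, ...) {
  cat(sprintf("<reference_labels> %s: %d residues (%d disordered, %d masked)\n",
              x$accession, length(x$labels), sum(x$labels == 1L & !x$mask),
              sum(x$mask)))
  invisible(x)
}

check_intervals_within <- function(annotation, length) {
  iv <- annotation$intervals
  if (nrow(iv) > 0L && (any(iv$start < 1L) || any(iv$end > length))) {
    stop("interval outside [1, ", length, "] for accession ",
         annotation$accession)
  }
}

#' Build a DisProt-style reference
#'
#' Residues inside any disorder interval are labelled disordered (1); all
#' other residues are labelled ordered (0). Nothing is masked.
#'
#' @param disorder annotation record (list with `accession` and an
#'   `intervals` data.frame), or `NULL` for no annotations.
#' @param length protein length in residues.
#' @param accession used when `disorder` is `NULL`.
#' @return A `reference_labels` object.
#' @export
build_disprot_reference <- function(disorder, length, accession = NULL) {
  acc <- if (!is.null(disorder)) disorder$accession else accession
  dis_mask <- if (!is.null(disorder)) {
    check_intervals_within(disorder, length)
    intervals_to_mask(disorder$intervals, length)
  } else logical(length)
  new_reference_labels(acc, as.integer(dis_mask), rep(FALSE, length),
                       ifelse(dis_mask, "disprot", "none"))
}

#' Build a DisProt-PDB-style reference
#'
#' Disorder-annotated residues are disordered (1) regardless of structural
#' coverage (annotation-vs-structure conflicts resolve to disorder);
#' covered but unannotated residues are ordered (0); residues with neither
#' annotation nor coverage are masked and excluded from all metrics.
#'
#' @param disorder,coverage annotation records (or `NULL`).
#' @param length protein length in residues.
#' @param accession used when both records are `NULL`.
#' @return A `reference_labels` object.
#' @export
build_disprot_pdb_reference <- function(disorder, coverage, length,
                                        accession = NULL) {
  acc <- if (!is.null(disorder)) disorder$accession
         else if (!is.null(coverage)) coverage$accession else accession
  dis_mask <- if (!is.null(disorder)) {
    check_intervals_within(disorder, length)
    intervals_to_mask(disorder$intervals, length)
  } else logical(length)
  cov_mask <- if (!is.null(coverage)) {
    check_intervals_within(coverage, length)
    intervals_to_mask(coverage$intervals, length)
  } else logical(length)
  masked <- !dis_mask & !cov_mask
  labels <- integer(length)
  labels[dis_mask] <- 1L
  prov <- rep("none", length)
  prov[cov_mask] <- "pdb"
  prov[dis_mask] <- "disprot"   # conflicts resolve to the disorder source
  new_reference_labels(acc, labels, masked, prov)
}

#' Masked fraction of a reference set
#'
#' @param references a single `reference_labels` object or a list of them.
#' @return A list with per-protein fractions and the pooled `overall`
#'   fraction of masked residues.
#' @export
masked_fraction <- function(references) {
  if (inherits(references, "reference_labels")) references <- list(references)
  per <- vapply(references, function(r) mean(r$mask), numeric(1))
  names(per) <- vapply(references, `[[`, character(1), "accession")
  total <- sum(vapply(references, function(r) sum(r$mask), numeric(1)))
  nres <- sum(vapply(references, function(r) length(r$mask), numeric(1)))
  list(per_protein = per, overall = total / nres)
}

#' Export reference labels as a per-residue TSV
#'
#' @param references list of `reference_labels`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_reference_table <- function(references, path) {
  rows <- do.call(rbind, lapply(references, function(r) {
    data.frame(accession = r$accession, position = seq_along(r$labels),
               label = r$labels, mask = as.integer(r$mask),
               provenance = r$provenance)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
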