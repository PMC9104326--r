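# Structure-derived disorder predictors: the naive secondary-structure rule
# (DSSPp), the continuous confidence transform tpLD = 1 - pLDDT/100, and
# the thresholded binary predictor pLDn with MCC-based threshold selection.

#' Naive secondary-structure disorder predictor (DSSPp)
#'
#' Residues assigned to helices (H/G/I), strands and bridges (E/B), or
#' hydrogen-bond-stabilised turns (T) are called ordered (0); bends (S) and
#' coil (-) are called disordered (1).
#'
#' @param ss8 an 8-class secondary-structure string.
#' @return Integer vector of binary calls (1 = disordered).
#' @export
dsspp_predict <- function(ss8) {
  chars <- strsplit(ss8, "")[[1]]
  ordered <- c("H", "G", "I", "E", "B", "T")
  disordered <- c("S", "-")
  bad <- setdiff(unique(chars), c(ordered, disordered))
  if (length(bad) > 0L) {
    stop("unknown secondary-structure character: ", paste(bad, collapse = ""))
  }
  as.integer(chars %in% disordered)
}

#' Transformed-confidence disorder score (tpLD)
#'
#' The continuous disorder score `1 - pLDDT/100`, mapping full confidence
#' (pLDDT 100) to 0 and no confidence (pLDDT 0) to 1. Inputs outside
#' \[0, 100\] are clamped with a warning.
#'
#' @param plddt numeric per-residue confidence in \[0, 100\].
#' @return Numeric disorder scores in \[0, 1\].
#' @export
tpld_predict <- function(plddt) {
  if (any(plddt < 0 | plddt > 100, na.rm = TRUE)) {
    warning("pLDDT values outside [0, 100] clamped")
    plddt <- pmin(100, pmax(0, plddt))
  }
  1 - plddt / 100
}

#' Thresholded binary disorder predictor (pLDn)
#'
#' Calls a residue ordered (0) when its pLDDT is at least `n`, disordered
#' (1) otherwise. The boundary `plddt == n` is ordered.
#'
#' @param plddt numeric per-residue confidence in \[0, 100\].
#' @param n threshold in \[0, 100\].
#' @return Integer vector of binary calls (1 = disordered).
#' @export
pldn_predict <- function(plddt, n) {
  stopifnot(n >= 0, n <= 100)
  as.integer(plddt < n)
}

#' Select the MCC-optimal confidence threshold
#'
#' Sweeps integer thresholds (by default 0..100) over the pooled evaluated
#' residues of a reference set, computing the Matthews correlation
#' coefficient of the pLDn calls at each, and returns the smallest
#' threshold attaining the maximum.
#'
#' @param plddt_profiles named list of per-residue pLDDT vectors.
#' @param references named list of `reference_labels` (masked residues are
#'   excluded).
#' @param n_grid integer thresholds to sweep.
#' @param dataset label stored in the result.
#' @return A list of class `threshold_search` with `best_n`, `best_mcc`,
#'   and the full `mcc_by_n` data.frame.
#' @export
select_threshold_mcc <- function(plddt_profiles, references,
                                 n_grid = 0:100, dataset = "dataset") {
  accs <- intersect(names(plddt_profiles), names(references))
  if (length(accs) == 0L) stop("no shared accessions")
  plddt <- unlist(lapply(accs, function(a) plddt_profiles[[a]]),
                  use.names = FALSE)
  lab <- unlist(lapply(accs, function(a) references[[a]]$labels),
                use.names = FALSE)
  msk <- unlist(lapply(accs, function(a) references[[a]]$mask),
                use.names = FALSE)
  plddt <- plddt[!msk]
  lab <- lab[!msk]
  if (length(unique(lab)) < 2L) {
    stop("reference contains a single class; MCC sweep undefined")
  }
  mccs <- vapply(n_grid, function(n) {
    pred <- as.integer(plddt < n)
    m <- mcc(confusion(lab, pred))
    if (is.na(m)) -Inf else m
  }, numeric(1))
  best <- which.max(mccs)  # which.max returns the first (smallest n) on ties
  structure(list(best_n = n_grid[best], best_mcc = mccs[best],
                 mcc_by_n = data.frame(n = n_grid, mcc = mccs),
                 dataset = dataset),
            class = "threshold_search")
}

#' @export
print.threshold_search <- function(x, ...) {
  cat(sprintf("<threshold_search> %s: best n = %d (MCC %.3f)\n",
              x$dataset, x$best_n, x$best_mcc))
  invisible(x)
}

#' Combine dataset-specific thresholds
#'
#' Arithmetic mean of the supplied thresholds, rounded half-up to an
#' integer (the combined predictor is named after this value, e.g. a 76/68
#' pair combines to 72).
#'
#' @param thresholds numeric vector of thresholds.
#' @return Integer combined threshold.
#' @export
combine_thresholds <- function(thresholds) {
  if (length(thresholds) == 0L) stop("no thresholds to combine")
  as.integer(round_half_up(mean(thresholds)))
}
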