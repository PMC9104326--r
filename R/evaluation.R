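# Benchmark statistics: confusion-matrix metrics, ROC/AUC,
# precision-recall/Fmax, per-protein RMSD, disorder content, protein
# classes, bootstrap summaries, and cross-predictor correlation. The
# disordered state (1) is the positive class throughout, and every metric
# is computed over evaluated (unmasked) residues only.

#' Confusion counts
#'
#' @param reference integer 0/1 reference labels.
#' @param prediction integer 0/1 calls of equal length.
#' @param mask optional logical; `TRUE` residues are excluded.
#' @return A list with `tp`, `fp`, `tn`, `fn` (1 = disordered = positive).
#' @export
confusion <- function(reference, prediction, mask = NULL) {
  if (length(reference) != length(prediction)) {
    stop("reference and prediction lengths differ")
  }
  if (!is.null(mask)) {
    reference <- reference[!mask]
    prediction <- prediction[!mask]
  }
  list(tp = sum(reference == 1L & prediction == 1L),
       fp = sum(reference == 0L & prediction == 1L),
       tn = sum(reference == 0L & prediction == 0L),
       fn = sum(reference == 1L & prediction == 0L))
}

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`. When the
#' reference holds a single class the value is undefined (`NA`); when both
#' classes are present but a denominator factor vanishes the conventional
#' value 0 is returned.
#'
#' @param counts list from [confusion()].
#' @return MCC in \[-1, 1\], or `NA` when undefined.
#' @export
mcc <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (tp + fn == 0L || tn + fp == 0L) return(NA_real_)  # single-class reference
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}

#' ROC curve and AUC
#'
#' Sweeps all distinct score values as thresholds (score >= threshold is
#' called disordered), producing a monotone ROC polygon; the AUC is its
#' trapezoidal area, which equals the pairwise concordance probability with
#' ties counted one half.
#'
#' @param reference integer 0/1 labels (1 = disordered).
#' @param scores numeric disorder scores, higher = more disordered.
#' @param mask optional logical exclusion mask.
#' @return A list of class `curve_result` with `points` (fpr, tpr),
#'   `thresholds`, and `auc` (`NA` when the reference is single-class).
#' @export
roc_auc <- function(reference, scores, mask = NULL) {
  if (!is.null(mask)) { reference <- reference[!mask]; scores <- scores[!mask] }
  npos <- sum(reference == 1L); nneg <- sum(reference == 0L)
  if (npos == 0L || nneg == 0L) {
    return(structure(list(points = NULL, thresholds = NULL, auc = NA_real_),
                     class = "curve_result"))
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; r <- reference[ord]
  cum_tp <- cumsum(r == 1L); cum_fp <- cumsum(r == 0L)
  idx <- cumsum(rle(s)$lengths)   # last index of each distinct score
  tpr <- c(0, cum_tp[idx] / npos)
  fpr <- c(0, cum_fp[idx] / nneg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr),
                 thresholds = c(Inf, thr), auc = auc),
            class = "curve_result")
}

#' Precision-recall curve and Fmax
#'
#' Precision and recall at every distinct score threshold (score >=
#' threshold called disordered); `fmax` is the maximum harmonic mean
#' 2PR/(P+R) over thresholds, which always reaches at least the
#' call-everything bound 2p/(1+p) at prevalence p.
#'
#' @inheritParams roc_auc
#' @return A list of class `curve_result` with `points` (recall,
#'   precision), `thresholds`, `fmax`, and the maximising `f_threshold`
#'   (`NA` when the reference has no positives).
#' @export
pr_fmax <- function(reference, scores, mask = NULL) {
  if (!is.null(mask)) { reference <- reference[!mask]; scores <- scores[!mask] }
  npos <- sum(reference == 1L)
  if (npos == 0L) {
    return(structure(list(points = NULL, thresholds = NULL,
                          fmax = NA_real_, f_threshold = NA_real_),
                     class = "curve_result"))
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; r <- reference[ord]
  idx <- cumsum(rle(s)$lengths)
  cum_tp <- cumsum(r == 1L)[idx]
  ncalled <- idx
  precision <- cum_tp / ncalled
  recall <- cum_tp / npos
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  best <- which.max(f1)
  structure(list(points = data.frame(recall = recall, precision = precision),
                 thresholds = s[idx], fmax = f1[best],
                 f_threshold = s[idx][best]),
            class = "curve_result")
}

#' @export
print.curve_result <- function(x, ...) {
  if (!is.null(x$auc)) cat(sprintf("<curve_result> ROC, AUC = %.3f\n", x$auc))
  else cat(sprintf("<curve_result> PR, Fmax = %.3f\n", x$fmax))
  invisible(x)
}

#' Per-protein RMSD between two residue vectors
#'
#' Root-mean-square difference `sqrt(mean((v - w)^2))` over evaluated
#' residues; for binary vectors this is the square root of the normalised
#' Hamming distance, and two independent fair coin flips give ~0.707.
#'
#' @param v,w numeric vectors in \[0, 1\] of equal length.
#' @param mask optional logical exclusion mask.
#' @return Non-negative RMSD, or `NA` when no residue survives masking.
#' @export
residue_rmsd <- function(v, w, mask = NULL) {
  if (length(v) != length(w)) stop("vector lengths differ")
  if (!is.null(mask)) { v <- v[!mask]; w <- w[!mask] }
  if (length(v) == 0L) return(NA_real_)
  sqrt(mean((v - w)^2))
}

#' Disorder content
#'
#' Fraction of evaluated residues labelled (or called) disordered.
#'
#' @param labels integer 0/1 vector.
#' @param mask optional logical exclusion mask.
#' @return Fraction in \[0, 1\].
#' @export
disorder_content <- function(labels, mask = NULL) {
  if (!is.null(mask)) labels <- labels[!mask]
  if (length(labels) == 0L) stop("no evaluated residues")
  mean(labels == 1L)
}

#' Protein class by disorder content
#'
#' @param content disorder content in \[0, 1\].
#' @param high cutoff above which a protein is highly disordered
#'   (strict inequality; default 0.90).
#' @param low cutoff below which a protein is highly ordered (default 0.10).
#' @return One of `"highly_disordered"`, `"highly_ordered"`, `"other"`.
#' @export
protein_class <- function(content, high = 0.90, low = 0.10) {
  stopifnot(content >= 0, content <= 1)
  if (content > high) "highly_disordered"
  else if (content < low) "highly_ordered"
  else "other"
}

#' Disorder-content histogram
#'
#' Histogram of per-protein disorder contents on \[0, 1\]. The default bin
#' width is 0.05 (a width of 0.5 would collapse the distribution into two
#' bins).
#'
#' @param contents numeric vector of per-protein disorder contents.
#' @param bin_width bin width on \[0, 1\].
#' @return data.frame with `mid`, `count`, `density`.
#' @export
disorder_content_histogram <- function(contents, bin_width = 0.05) {
  contents <- contents[is.finite(contents)]
  stopifnot(all(contents >= 0 & contents <= 1), bin_width > 0, bin_width <= 1)
  h <- graphics::hist(contents, breaks = seq(0, 1 + bin_width, by = bin_width),
                      plot = FALSE, right = FALSE)
  data.frame(mid = h$mids, count = h$counts, density = h$density)
}

#' Bootstrap mean and standard error
#'
#' Resamples `sample_size` values with replacement `n_samples` times and
#' reports the mean of the resample means and their standard deviation
#' (the bootstrap standard error). A fixed seed reproduces the summary
#' exactly without disturbing the caller's RNG stream.
#'
#' @param values numeric vector (non-empty).
#' @param n_samples number of bootstrap resamples (default 10000).
#' @param sample_size resample size (default 60, the protein-level
#'   convention; residue-level summaries use 500).
#' @param seed integer seed.
#' @return A list with `mean`, `stderr`, `n_samples`, `sample_size`, `seed`.
#' @export
bootstrap_summary <- function(values, n_samples = 10000L, sample_size = 60L,
                              seed = 1L) {
  if (length(values) == 0L) stop("no values to bootstrap")
  means <- with_seed(seed, {
    draws <- sample.int(length(values), n_samples * sample_size, replace = TRUE)
    colMeans(matrix(values[draws], nrow = sample_size))
  })
  list(mean = mean(means), stderr = sd(means),
       n_samples = as.integer(n_samples), sample_size = as.integer(sample_size),
       seed = as.integer(seed))
}

#' Cross-predictor correlation of per-protein RMSD
#'
#' Pearson correlation and least-squares slope/intercept for every pair of
#' predictors over a shared protein set.
#'
#' @param rmsd_table data.frame or matrix; rows = proteins, columns =
#'   predictors, entries = per-protein RMSD.
#' @return data.frame with one row per predictor pair: `a`, `b`, `r`,
#'   `slope`, `intercept` (all `NA` when fewer than 3 shared proteins).
#' @export
predictor_correlation <- function(rmsd_table) {
  rmsd_table <- as.data.frame(rmsd_table)
  preds <- names(rmsd_table)
  if (length(preds) < 2L) stop("need at least two predictors")
  out <- list()
  for (i in seq_along(preds)) {
    for (j in seq_along(preds)) {
      if (j <= i) next
      x <- rmsd_table[[i]]; y <- rmsd_table[[j]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3L) {
        out[[length(out) + 1L]] <- data.frame(
          a = preds[i], b = preds[j], r = NA_real_,
          slope = NA_real_, intercept = NA_real_)
      } else {
        fit <- lm(y[ok] ~ x[ok])
        out[[length(out) + 1L]] <- data.frame(
          a = preds[i], b = preds[j], r = cor(x[ok], y[ok]),
          slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]))
      }
    }
  }
  do.call(rbind, out)
}
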