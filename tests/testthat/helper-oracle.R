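# Shared test helpers: an independent reference secondary-structure oracle
# (mdtraj's DSSP, called through the system python) and small brute-force
# metric oracles used for equivalence tests.

# Run the reference DSSP implementation on PDB files; returns one
# 8-class string per file (all chains concatenated, coil as '-').
reference_dssp <- function(pdb_paths) {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  stopifnot(nzchar(py))
  script <- tempfile(fileext = ".py")
  out <- tempfile(fileext = ".txt")
  writeLines(c(
    "import sys, mdtraj",
    "paths = sys.argv[1].split(',')",
    "res = []",
    "for p in paths:",
    "    ss = mdtraj.compute_dssp(mdtraj.load(p), simplified=False)[0]",
    "    res.append(''.join(ss).replace(' ', '-'))",
    "open(sys.argv[2], 'w').write('\\n'.join(res) + '\\n')"
  ), script)
  status <- system2(py, c(script, paste(pdb_paths, collapse = ","), out),
                    stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0)
  readLines(out)
}

# Brute-force AUC: pairwise concordance probability with ties counted 1/2.
concordance_auc <- function(reference, scores) {
  pos <- scores[reference == 1L]
  neg <- scores[reference == 0L]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Naive exhaustive MCC threshold scan, independent of the package's sweep.
naive_best_threshold <- function(plddt, labels, grid = 0:100) {
  best_n <- NA_integer_
  best <- -Inf
  for (n in grid) {
    pred <- as.integer(plddt < n)
    tp <- sum(labels == 1 & pred == 1); fp <- sum(labels == 0 & pred == 1)
    tn <- sum(labels == 0 & pred == 0); fn <- sum(labels == 1 & pred == 0)
    den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    m <- if (den == 0) 0 else (tp * tn - fp * fn) / den
    if (m > best) { best <- m; best_n <- n }
  }
  list(best_n = best_n, best_mcc = best)
}

# random rigid rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_res <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_res)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# minimal reference_labels object for metric tests
new_ref <- function(labels, mask = NULL, acc = "P") {
  if (is.null(mask)) mask <- rep(FALSE, length(labels))
  structure(list(accession = acc, labels = as.integer(labels),
                 mask = mask, provenance = rep("disprot", length(labels))),
            class = "reference_labels")
}

tiny_interval_record <- function(acc, starts, ends, kind = "disorder") {
  list(accession = acc, kind = kind,
       intervals = data.frame(start = as.integer(starts),
                              end = as.integer(ends)))
}
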