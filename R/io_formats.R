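#' @importFrom stats cor density lm coef qnorm plogis rnorm runif sd setNames optim
#' @importFrom utils read.table write.table head tail
#' @importFrom graphics hist
NULL

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Construct a structure model
#'
#' A `structure_model` holds, per chain, the backbone atoms (N, CA, C, O) and
#' the residue-level confidence score (pLDDT, 0-100) of a predicted protein
#' model. Coordinates are in Angstrom; missing atoms are `NA` rows and flag
#' the residue as incomplete.
#'
#' @param chains named list; each element a list with integer `resno`,
#'   character `resid` (3-letter codes), numeric `plddt`, and `n x 3`
#'   coordinate matrices `N`, `CA`, `C`, `O`.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(chains) {
  stopifnot(is.list(chains), length(chains) > 0L)
  chains <- lapply(chains, function(ch) {
    n <- length(ch$resno)
    stopifnot(length(ch$plddt) == n)
    for (a in BACKBONE_ATOMS) {
      if (is.null(ch[[a]])) ch[[a]] <- matrix(NA_real_, n, 3)
      stopifnot(nrow(ch[[a]]) == n, ncol(ch[[a]]) == 3)
    }
    if (is.null(ch$resid)) ch$resid <- rep("ALA", n)
    if (is.unsorted(ch$resno, strictly = TRUE)) {
      stop("residue indices must be strictly increasing within a chain")
    }
    ch$incomplete <- vapply(seq_len(n), function(i) {
      any(vapply(BACKBONE_ATOMS, function(a) anyNA(ch[[a]][i, ]), logical(1)))
    }, logical(1))
    ch
  })
  structure(list(chains = chains), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  nres <- vapply(x$chains, function(ch) length(ch$resno), integer(1))
  cat(sprintf("<structure_model> %d chain(s), %d residues\n",
              length(x$chains), sum(nres)))
  for (nm in names(x$chains)) {
    ch <- x$chains[[nm]]
    cat(sprintf("  chain %s: %d residues, pLDDT %.1f-%.1f, %d incomplete\n",
                nm, length(ch$resno), min(ch$plddt), max(ch$plddt),
                sum(ch$incomplete)))
  }
  invisible(x)
}

n_residues <- function(model) {
  sum(vapply(model$chains, function(ch) length(ch$resno), integer(1)))
}

#' Read a predicted structure with confidence in the B-factor field
#'
#' Parses a PDB or mmCIF file into a [structure_model()]. The per-residue
#' confidence score (pLDDT for predicted models) is taken from the B-factor
#' of the CA atom, falling back to the mean over present backbone atoms.
#' Only the first model and first alternate location are read. Residues
#' missing any backbone atom are flagged incomplete but keep their score.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"`, or `"cif"`.
#' @return A `structure_model`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e))
  )
  at <- parsed$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A", "."), , drop = FALSE]
  at <- at[at$elety %in% BACKBONE_ATOMS, , drop = FALSE]
  if (nrow(at) == 0L) stop("no protein residues found in '", path, "'")
  at$chain[is.na(at$chain)] <- "A"
  if (any(at$b < 0 | at$b > 100, na.rm = TRUE)) {
    warning("B-factor values outside [0, 100]; not a pLDDT-carrying model?")
  }
  chains <- list()
  for (cid in unique(at$chain)) {
    ca <- at[at$chain == cid, , drop = FALSE]
    resno <- sort(unique(ca$resno))
    n <- length(resno)
    ch <- list(resno = as.integer(resno),
               resid = character(n),
               plddt = numeric(n))
    for (a in BACKBONE_ATOMS) ch[[a]] <- matrix(NA_real_, n, 3)
    for (i in seq_len(n)) {
      rows <- ca[ca$resno == resno[i], , drop = FALSE]
      ch$resid[i] <- rows$resid[1]
      bs <- numeric(0)
      for (a in BACKBONE_ATOMS) {
        r <- rows[rows$elety == a, , drop = FALSE]
        if (nrow(r) >= 1L) {
          ch[[a]][i, ] <- c(r$x[1], r$y[1], r$z[1])
          bs[a] <- r$b[1]
        }
      }
      ch$plddt[i] <- if ("CA" %in% names(bs)) bs[["CA"]] else mean(bs)
    }
    chains[[cid]] <- ch
  }
  structure_model(chains)
}

#' Write a structure model as a fixed-column PDB file
#'
#' Backbone atoms only, one ATOM record per atom, B-factor printed with two
#' decimals (carrying the residue pLDDT), `TER` between chains, final `END`.
#'
#' @param model a [structure_model()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  if (n_residues(model) == 0L) stop("refusing to write an empty model")
  lines <- character(0)
  serial <- 0L
  for (cid in names(model$chains)) {
    ch <- model$chains[[cid]]
    if (any(ch$resno > 9999L)) {
      stop("residue index exceeds 9999; not representable in PDB columns")
    }
    for (i in seq_along(ch$resno)) {
      for (a in BACKBONE_ATOMS) {
        xyz <- ch[[a]][i, ]
        if (anyNA(xyz)) next
        serial <- serial + 1L
        name_fmt <- sprintf(" %-3s", a)  # backbone names start in column 14
        lines <- c(lines, sprintf(
          "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, name_fmt, ch$resid[i], substr(cid, 1, 1),
          ch$resno[i], xyz[1], xyz[2], xyz[3], 1.0, ch$plddt[i],
          substr(a, 1, 1)))
      }
    }
    lines <- c(lines, "TER")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read per-residue disorder predictions in CAID text format
#'
#' The format alternates `>`-prefixed accession headers with tab-separated
#' per-residue rows: 1-based position, one-letter residue, score in
#' \[0, 1\], and an optional binary label. Positions must be contiguous
#' from 1.
#'
#' @param path file path.
#' @return A named list of prediction records, each a list with `accession`,
#'   `position`, `residue`, `score`, and `label` (NULL when absent).
#' @export
read_caid_predictions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L || !startsWith(lines[1], ">")) {
    stop("CAID file must start with a '>' accession header")
  }
  out <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    if (length(cur$position) == 0L) {
      stop("accession ", cur$accession, " has no prediction rows")
    }
    if (!identical(cur$position, seq_along(cur$position))) {
      stop("non-contiguous positions for accession ", cur$accession)
    }
    if (all(is.na(cur$label))) cur$label <- NULL else cur$label <- as.integer(cur$label)
    cur
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (startsWith(line, ">")) {
      if (!is.null(cur)) out[[cur$accession]] <- flush(cur)
      cur <- list(accession = trimws(substring(line, 2)),
                  position = integer(0), residue = character(0),
                  score = numeric(0), label = integer(0))
    } else {
      fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(fields) < 3L) {
        stop("line ", ln, ": expected at least 3 tab-separated fields")
      }
      pos <- suppressWarnings(as.integer(fields[1]))
      score <- suppressWarnings(as.numeric(fields[3]))
      if (is.na(pos) || is.na(score)) {
        stop("line ", ln, ": malformed position or score")
      }
      if (score < 0 || score > 1) {
        stop("line ", ln, " (", cur$accession, "): score ", fields[3],
             " outside [0, 1]")
      }
      lab <- if (length(fields) >= 4L && nzchar(fields[4])) {
        v <- suppressWarnings(as.integer(fields[4]))
        if (is.na(v) || !v %in% c(0L, 1L)) {
          stop("line ", ln, ": binary label must be 0 or 1")
        }
        v
      } else NA_integer_
      cur$position <- c(cur$position, pos)
      cur$residue <- c(cur$residue, fields[2])
      cur$score <- c(cur$score, score)
      cur$label <- c(cur$label, lab)
    }
  }
  out[[cur$accession]] <- flush(cur)
  out
}

#' Write predictions in CAID text format
#'
#' @param predictions list as returned by [read_caid_predictions()]; entries
#'   need `accession` and `score`, optionally `residue` and `label`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_caid_predictions <- function(predictions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in predictions) {
    n <- length(p$score)
    res <- if (is.null(p$residue)) rep("A", n) else p$residue
    writeLines(paste0(">", p$accession), con)
    rows <- sprintf("%d\t%s\t%.3f", seq_len(n), res, p$score)
    if (!is.null(p$label)) rows <- paste0(rows, "\t", p$label)
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read an interval annotation table
#'
#' Tab-separated columns `accession`, `start`, `end` (1-based inclusive,
#' optional header line). Intervals may overlap; they are merged downstream
#' when expanded to residue masks.
#'
#' @param path file path.
#' @param kind annotation kind, `"disorder"` or `"pdb_coverage"`.
#' @return A named list per accession: list with `accession`, `kind`, and an
#'   `intervals` data.frame (`start`, `end`).
#' @export
read_intervals <- function(path, kind = c("disorder", "pdb_coverage")) {
  kind <- match.arg(kind)
  raw <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = "character", col.names = c("accession", "start", "end"))
  if (nrow(raw) > 0L && tolower(raw$accession[1]) == "accession") {
    raw <- raw[-1L, , drop = FALSE]
  }
  start <- suppressWarnings(as.numeric(raw$start))
  end <- suppressWarnings(as.numeric(raw$end))
  if (anyNA(start) || anyNA(end) ||
      any(start != floor(start)) || any(end != floor(end))) {
    stop("interval bounds must be integers")
  }
  if (any(start < 1) || any(start > end)) {
    bad <- which(start < 1 | start > end)[1]
    stop(sprintf("invalid interval (%s, %s) for accession %s",
                 raw$start[bad], raw$end[bad], raw$accession[bad]))
  }
  out <- list()
  for (acc in unique(raw$accession)) {
    sel <- raw$accession == acc
    out[[acc]] <- list(accession = acc, kind = kind,
                       intervals = data.frame(start = as.integer(start[sel]),
                                              end = as.integer(end[sel])))
  }
  out
}

#' Write an interval annotation table
#'
#' @param annotations list as returned by [read_intervals()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_intervals <- function(annotations, path) {
  rows <- do.call(rbind, lapply(annotations, function(a) {
    if (nrow(a$intervals) == 0L) return(NULL)
    data.frame(accession = a$accession, start = a$intervals$start,
               end = a$intervals$end)
  }))
  if (is.null(rows)) rows <- data.frame(accession = character(0),
                                        start = integer(0), end = integer(0))
  write.table(rows, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a per-residue label/score table as TSV
#'
#' Standard flat export used by the pipeline: columns `accession`,
#' `position`, `reference_label`, `score`, `call`, `mask`.
#'
#' @param table data.frame with those columns.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_residue_table <- function(table, path) {
  need <- c("accession", "position", "reference_label", "score", "call", "mask")
  stopifnot(all(need %in% names(table)))
  write.table(table[, need], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
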