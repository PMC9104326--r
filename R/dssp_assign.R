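# Kabsch-Sander secondary-structure assignment from backbone geometry.
#
# The hydrogen-bond model is electrostatic: partial charges on the C=O and
# N-H dipoles give E = 27.888 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)
# kcal/mol, and a bond is recorded when E < -0.5 kcal/mol. Amide hydrogens
# are reconstructed from the preceding peptide unit. Cooperating bonds then
# define turns, helices, bridges and ladders in the classic 8-class
# alphabet {H, G, I, E, B, T, S, -}.

HB_Q <- 27.888          # kcal/mol * Angstrom, coupling constant
HB_CUTOFF <- -0.5       # kcal/mol, bond acceptance threshold
HB_MIN_DIST <- 0.5      # Angstrom, clamp against coincident atoms
CHAIN_BREAK_CN <- 2.5   # Angstrom, max peptide C-N distance
BEND_KAPPA <- 70        # degrees, CA pseudo-angle threshold for 'S'
CA_NEIGHBOUR_CUTOFF <- 9  # Angstrom, pair pre-filter for bond search

#' Electrostatic hydrogen-bond energy
#'
#' Energy of a putative hydrogen bond between a backbone C=O group (acceptor
#' side) and an N-H group (donor side), in kcal/mol. Pairwise distances are
#' clamped below at 0.5 Angstrom to avoid singularities on malformed input
#' (with a warning).
#'
#' @param n,h,c,o numeric length-3 coordinates (Angstrom) of the donor N and
#'   H and the acceptor C and O.
#' @return Energy in kcal/mol; values below -0.5 qualify as bonds.
#' @export
hbond_energy <- function(n, h, c, o) {
  d <- c(vec_norm(o - n), vec_norm(c - h), vec_norm(o - h), vec_norm(c - n))
  if (any(!is.finite(d))) stop("non-finite coordinates in hbond_energy")
  if (any(d < HB_MIN_DIST)) {
    warning("near-coincident atoms; distances clamped to 0.5 Angstrom")
    d <- pmax(d, HB_MIN_DIST)
  }
  HB_Q * (1 / d[1] + 1 / d[2] - 1 / d[3] - 1 / d[4])
}

#' Reconstruct backbone amide hydrogens
#'
#' Places the amide H of residue i (i > 1 within a contiguous segment,
#' non-proline) at N_i + unit(C_(i-1) - O_(i-1)) * 1.0 Angstrom, i.e. 1
#' Angstrom from N along the direction of the preceding carbonyl dipole.
#' Prolines, segment-start residues, and residues whose preceding C/O are
#' missing carry no donor hydrogen.
#'
#' @param model a [structure_model()].
#' @return The model with an `H` coordinate matrix per chain (`NA` rows for
#'   donor-incapable residues).
#' @export
place_amide_hydrogens <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  for (cid in names(model$chains)) {
    ch <- model$chains[[cid]]
    n <- length(ch$resno)
    H <- matrix(NA_real_, n, 3)
    if (n >= 2L) {
      for (i in 2:n) {
        if (ch$resid[i] == "PRO") next
        if (anyNA(ch$N[i, ]) || anyNA(ch$C[i - 1, ]) || anyNA(ch$O[i - 1, ])) next
        # contiguity: the peptide bond to i-1 must exist
        cn <- vec_norm(ch$N[i, ] - ch$C[i - 1, ])
        if (!is.finite(cn) || cn > CHAIN_BREAK_CN) next
        H[i, ] <- ch$N[i, ] + unit_vec(ch$C[i - 1, ] - ch$O[i - 1, ])
      }
    }
    model$chains[[cid]]$H <- H
  }
  model
}

# Flatten a model into one residue table with segment ids (new segment at
# chain starts, chain breaks, and around incomplete residues).
flatten_residues <- function(model) {
  rows <- list()
  seg <- 0L
  for (cid in names(model$chains)) {
    ch <- model$chains[[cid]]
    n <- length(ch$resno)
    seg <- seg + 1L
    segs <- integer(n)
    for (i in seq_len(n)) {
      if (i > 1L) {
        broken <- ch$incomplete[i] || ch$incomplete[i - 1] ||
          anyNA(ch$C[i - 1, ]) || anyNA(ch$N[i, ]) ||
          vec_norm(ch$N[i, ] - ch$C[i - 1, ]) > CHAIN_BREAK_CN
        if (broken) seg <- seg + 1L
      }
      segs[i] <- seg
    }
    rows[[cid]] <- list(chain = rep(cid, n), pos = seq_len(n), segment = segs,
                        incomplete = ch$incomplete)
  }
  list(chain = unlist(lapply(rows, `[[`, "chain"), use.names = FALSE),
       pos = unlist(lapply(rows, `[[`, "pos"), use.names = FALSE),
       segment = unlist(lapply(rows, `[[`, "segment"), use.names = FALSE),
       incomplete = unlist(lapply(rows, `[[`, "incomplete"), use.names = FALSE))
}

# Hydrogen-bond adjacency: hb[i, j] is TRUE when the CO of residue i accepts
# the NH of residue j with energy below the cutoff.
hbond_matrix <- function(model, flat) {
  n <- length(flat$pos)
  get_mat <- function(atom) {
    do.call(rbind, lapply(names(model$chains), function(cid) {
      model$chains[[cid]][[atom]]
    }))
  }
  CA <- get_mat("CA"); N <- get_mat("N"); C <- get_mat("C")
  O <- get_mat("O"); Hm <- get_mat("H")
  hb <- matrix(FALSE, n, n)
  has_co <- !is.na(C[, 1]) & !is.na(O[, 1]) & !flat$incomplete
  has_nh <- !is.na(N[, 1]) & !is.na(Hm[, 1]) & !flat$incomplete
  ca_ok <- !is.na(CA[, 1])
  for (i in which(has_co & ca_ok)) {
    # cheap spatial prefilter on CA-CA distance
    d2 <- (CA[, 1] - CA[i, 1])^2 + (CA[, 2] - CA[i, 2])^2 + (CA[, 3] - CA[i, 3])^2
    cand <- which(has_nh & ca_ok & d2 < CA_NEIGHBOUR_CUTOFF^2)
    for (j in cand) {
      if (flat$chain[j] == flat$chain[i] && abs(flat$pos[j] - flat$pos[i]) <= 1L) next
      rON <- max(vec_norm(O[i, ] - N[j, ]), HB_MIN_DIST)
      rCH <- max(vec_norm(C[i, ] - Hm[j, ]), HB_MIN_DIST)
      rOH <- max(vec_norm(O[i, ] - Hm[j, ]), HB_MIN_DIST)
      rCN <- max(vec_norm(C[i, ] - N[j, ]), HB_MIN_DIST)
      e <- HB_Q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      if (e < HB_CUTOFF) hb[i, j] <- TRUE
    }
  }
  hb
}

#' Assign 8-class secondary structure
#'
#' From-scratch Kabsch-Sander assignment: hydrogen bonds from the
#' electrostatic model feed n-turn (n = 3, 4, 5), helix, bridge and ladder
#' patterns; CA pseudo-angles above 70 degrees give bends. Classes are
#' resolved with priority H > E/B > G > I > T > S. Chains shorter than 5
#' residues are returned as all '-' with a warning; incomplete residues get
#' '-'.
#'
#' @param model a [structure_model()]; hydrogens are placed automatically
#'   when absent.
#' @return Named character vector: one 8-class string per chain, over the
#'   alphabet `H G I E B T S -`.
#' @export
assign_ss8 <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  if (is.null(model$chains[[1]]$H)) model <- place_amide_hydrogens(model)
  flat <- flatten_residues(model)
  n <- length(flat$pos)
  lens <- vapply(model$chains, function(ch) length(ch$resno), integer(1))
  if (all(lens < 5L)) {
    warning("all chains shorter than 5 residues; no structure assignable")
    return(setNames(vapply(lens, function(l) paste(rep("-", l), collapse = ""),
                           character(1)), names(model$chains)))
  }
  hb <- hbond_matrix(model, flat)

  same_seg_run <- function(i, j) {
    i >= 1L && j <= n && flat$segment[i] == flat$segment[j]
  }
  # n-turns: CO of i bonded to NH of i+k within one segment
  turn <- list()
  for (k in 3:5) {
    tk <- logical(n)
    for (i in seq_len(n)) {
      if (i + k <= n && same_seg_run(i, i + k) && hb[i, i + k]) tk[i] <- TRUE
    }
    turn[[as.character(k)]] <- tk
  }

  # helices: two consecutive n-turns start a minimal helix covering i..i+n-1
  helix <- list()
  for (k in 3:5) {
    hk <- logical(n)
    tk <- turn[[as.character(k)]]
    for (i in 2:n) {
      if (tk[i] && tk[i - 1] && same_seg_run(i, i + k - 1L)) {
        hk[i:(i + k - 1L)] <- TRUE
      }
    }
    helix[[as.character(k)]] <- hk
  }

  # bridges
  prev_ok <- function(i) i > 1L && flat$segment[i - 1L] == flat$segment[i]
  next_ok <- function(i) i < n && flat$segment[i + 1L] == flat$segment[i]
  bridges <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (flat$chain[i] == flat$chain[j] && j - i < 3L) next
      par <- (prev_ok(i) && next_ok(i) && hb[i - 1L, j] && hb[j, i + 1L]) ||
             (prev_ok(j) && next_ok(j) && hb[j - 1L, i] && hb[i, j + 1L])
      anti <- (hb[i, j] && hb[j, i]) ||
              (prev_ok(i) && next_ok(i) && prev_ok(j) && next_ok(j) &&
               hb[i - 1L, j + 1L] && hb[j - 1L, i + 1L])
      if (par || anti) {
        bridges[[length(bridges) + 1L]] <- c(i = i, j = j,
                                             type = if (par) 1L else 2L)
      }
    }
  }
  in_ladder <- logical(n)   # residues in extended (>= 2 bridge) ladders -> E
  in_bridge <- logical(n)   # residues in any bridge -> at least B
  if (length(bridges) > 0L) {
    bi <- vapply(bridges, `[[`, integer(1), "i")
    bj <- vapply(bridges, `[[`, integer(1), "j")
    bt <- vapply(bridges, `[[`, integer(1), "type")
    in_bridge[c(bi, bj)] <- TRUE
    linked <- logical(length(bridges))
    for (a in seq_along(bridges)) {
      for (b in seq_along(bridges)) {
        if (a == b || bt[a] != bt[b]) next
        if (bt[a] == 1L) {  # parallel ladder: both indices advance
          if (bi[b] == bi[a] + 1L && bj[b] == bj[a] + 1L) linked[c(a, b)] <- TRUE
        } else {            # antiparallel ladder: indices advance oppositely
          if (bi[b] == bi[a] + 1L && bj[b] == bj[a] - 1L) linked[c(a, b)] <- TRUE
        }
      }
    }
    in_ladder[c(bi[linked], bj[linked])] <- TRUE
  }

  # bends: CA pseudo-angle over a 5-residue window
  CA <- do.call(rbind, lapply(model$chains, function(ch) ch$CA))
  bend <- logical(n)
  for (i in seq_len(n)) {
    if (i < 3L || i + 2L > n) next
    if (flat$segment[i - 2L] != flat$segment[i + 2L]) next
    u <- CA[i, ] - CA[i - 2L, ]
    v <- CA[i + 2L, ] - CA[i, ]
    if (anyNA(u) || anyNA(v)) next
    cosk <- sum(u * v) / (vec_norm(u) * vec_norm(v))
    kappa <- acos(pmin(1, pmax(-1, cosk))) * 180 / pi
    if (kappa > BEND_KAPPA) bend[i] <- TRUE
  }

  # turn region: interior residues of any n-turn
  turn_region <- logical(n)
  for (k in 3:5) {
    for (i in which(turn[[as.character(k)]])) {
      if (same_seg_run(i, i + k)) {
        turn_region[(i + 1L):(i + k - 1L)] <- TRUE
      }
    }
  }

  # resolve with priority H > E/B > G > I > T > S (assign low to high)
  ss <- rep("-", n)
  ss[bend] <- "S"
  ss[turn_region] <- "T"
  ss[helix[["5"]]] <- "I"
  ss[helix[["3"]]] <- "G"
  ss[in_bridge] <- "B"
  ss[in_ladder] <- "E"
  ss[helix[["4"]]] <- "H"
  ss[flat$incomplete] <- "-"

  out <- character(0)
  for (cid in names(model$chains)) {
    sel <- flat$chain == cid
    s <- paste(ss[sel], collapse = "")
    if (sum(sel) < 5L) s <- paste(rep("-", sum(sel)), collapse = "")
    out[cid] <- s
  }
  short <- lens < 5L
  if (any(short)) warning("chains shorter than 5 residues assigned all '-': ",
                          paste(names(model$chains)[short], collapse = ", "))
  out
}

#' Reduce an 8-class secondary-structure string to 4 classes
#'
#' Maps helices H/G/I to `H`, strand and bridge E/B to `E`, turn T to `T`,
#' and bend/coil S/- to `C`.
#'
#' @param ss8 character vector of 8-class strings.
#' @return Character vector of 4-class strings of equal lengths.
#' @export
reduce_ss <- function(ss8) {
  vapply(ss8, function(s) {
    if (nchar(s) == 0L) return("")
    chars <- strsplit(s, "")[[1]]
    map <- c(H = "H", G = "H", I = "H", E = "E", B = "E",
             T = "T", S = "C", "-" = "C")
    red <- map[chars]
    if (anyNA(red)) {
      stop("unknown secondary-structure character: ",
           paste(unique(chars[is.na(red)]), collapse = ""))
    }
    paste(red, collapse = "")
  }, character(1), USE.NAMES = !is.null(names(ss8)))
}

#' Read a classic DSSP output file
#'
#' Minimal reader for the classic fixed-column `.dssp` table dialect, so a
#' reference implementation's assignment can be substituted for the built-in
#' one. Only the residue number, chain, and summary structure column are
#' read; chain-break rows (`!`) are skipped.
#'
#' @param path file path.
#' @return Named character vector: one 8-class string per chain (blank
#'   structure columns become '-').
#' @export
read_dssp_file <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0L) stop("not a classic DSSP file: ", path)
  body <- lines[(hdr[1] + 1L):length(lines)]
  chains <- list()
  for (line in body) {
    if (nchar(line) < 17L) next
    aa <- substr(line, 14, 14)
    if (aa == "!") next
    cid <- substr(line, 12, 12)
    sschar <- substr(line, 17, 17)
    if (sschar == " ") sschar <- "-"
    if (cid == " ") cid <- "A"
    chains[[cid]] <- c(chains[[cid]], sschar)
  }
  vapply(chains, paste, character(1), collapse = "")
}
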