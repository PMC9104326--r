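# Secondary-structure-codon analysis: how per-residue confidence relates to
# local secondary structure. A codon is the triplet of reduced classes at a
# residue and its two neighbours; distributions of confidence per class and
# per codon summarise where high- and low-confidence residues live.

#' Secondary-structure codons
#'
#' The codon at interior residue i is the triplet `(s[i-1], s[i], s[i+1])`
#' of reduced classes; chain termini carry no codon.
#'
#' @param reduced a 4-class (H/E/T/C) secondary-structure string.
#' @return data.frame with `center` (1-based residue position) and
#'   `triplet`; zero rows (with a warning) for strings shorter than 3.
#' @export
ss_codons <- function(reduced) {
  n <- nchar(reduced)
  if (n < 3L) {
    warning("string shorter than 3 residues has no codons")
    return(data.frame(center = integer(0), triplet = character(0)))
  }
  chars <- strsplit(reduced, "")[[1]]
  centers <- 2:(n - 1L)
  data.frame(center = centers,
             triplet = paste0(chars[centers - 1L], chars[centers],
                              chars[centers + 1L]))
}

scott_bandwidth <- function(x) {
  n <- length(x)
  if (n < 2L || sd(x) == 0) return(1)
  sd(x) * n^(-1 / 5)
}

class_distribution <- function(label, values, bootstrap_seed = 1L,
                               bin_width = 0.5) {
  breaks <- seq(0, 100 + bin_width, by = bin_width)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  kde <- if (length(values) >= 2L && sd(values) > 0) {
    density(values, bw = scott_bandwidth(values), n = 512, from = 0, to = 100)
  } else NULL
  boot <- if (length(values) >= 2L) {
    bootstrap_summary(values, n_samples = 10000L, sample_size = 500L,
                      seed = bootstrap_seed)
  } else NULL
  list(label = label, n = length(values), values = values,
       mean = mean(values), skewness = sample_skewness(values),
       histogram = data.frame(mid = h$mids, density = h$density),
       kde = if (is.null(kde)) NULL else data.frame(x = kde$x, y = kde$y),
       bootstrap = boot,
       frac_below_50 = mean(values < 50))
}

#' Confidence distributions per secondary-structure class
#'
#' Groups per-residue pLDDT values by reduced class (H/E/T/C) and
#' summarises each group: mean with a residue-level bootstrap (10,000
#' resamples of size 500), skewness, histogram, and a Gaussian KDE with
#' Scott's-rule bandwidth on a 512-point grid over \[0, 100\]. Empty
#' classes are omitted with a warning.
#'
#' @param reduced 4-class string (or vector of strings, concatenated).
#' @param plddt numeric vector matching the total string length.
#' @param bootstrap_seed seed for the bootstrap summaries.
#' @param bin_width histogram bin width in pLDDT units.
#' @return Named list of per-class distribution summaries.
#' @export
plddt_by_class <- function(reduced, plddt, bootstrap_seed = 1L,
                           bin_width = 0.5) {
  chars <- unlist(strsplit(reduced, ""), use.names = FALSE)
  if (length(chars) != length(plddt)) {
    stop("secondary-structure and confidence lengths differ")
  }
  out <- list()
  for (cl in c("H", "E", "T", "C")) {
    sel <- chars == cl
    if (!any(sel)) {
      warning("no residues in class ", cl)
      next
    }
    out[[cl]] <- class_distribution(cl, plddt[sel], bootstrap_seed, bin_width)
  }
  out
}

#' Confidence distributions per secondary-structure codon
#'
#' @param codons data.frame from [ss_codons()] (possibly concatenated over
#'   proteins, with `triplet` and `center` columns aligned to `plddt`).
#' @param plddt numeric values for the codon centres, same row order.
#' @param min_count codons with fewer observations are flagged
#'   `low_support` (default 25).
#' @param bootstrap_seed seed for bootstrap summaries.
#' @return Named list per observed triplet: distribution summary plus
#'   `low_support` flag.
#' @export
plddt_by_codon <- function(codons, plddt, min_count = 25L,
                           bootstrap_seed = 1L) {
  stopifnot(nrow(codons) == length(plddt))
  out <- list()
  for (tr in sort(unique(codons$triplet))) {
    sel <- codons$triplet == tr
    d <- class_distribution(tr, plddt[sel], bootstrap_seed)
    d$low_support <- sum(sel) < min_count
    out[[tr]] <- d
  }
  out
}

#' Detect KDE bimodality
#'
#' Reports whether a class distribution's KDE curve has two local maxima
#' separated by at least `min_separation` pLDDT units, and returns the peak
#' locations.
#'
#' @param dist a distribution summary from [plddt_by_class()].
#' @param min_separation minimum peak separation (default 10).
#' @return List with `bimodal` and `peaks` (x locations of local maxima,
#'   strongest first).
#' @export
kde_bimodality <- function(dist, min_separation = 10) {
  if (is.null(dist$kde)) return(list(bimodal = FALSE, peaks = numeric(0)))
  y <- dist$kde$y; x <- dist$kde$x
  n <- length(y)
  loc <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (length(loc) == 0L) return(list(bimodal = FALSE, peaks = numeric(0)))
  loc <- loc[order(y[loc], decreasing = TRUE)]
  peaks <- x[loc]
  bimodal <- FALSE
  if (length(peaks) >= 2L) {
    # keep peaks with meaningful mass relative to the strongest
    strong <- peaks[y[loc] > 0.1 * y[loc[1]]]
    bimodal <- length(strong) >= 2L &&
      max(strong) - min(strong) >= min_separation
    peaks <- strong
  }
  list(bimodal = bimodal, peaks = peaks)
}

#' Min-max normalised confidence
#'
#' Per-segment normalisation `(x - min) / (max - min)` used when comparing
#' confidence to structure propensity along a peptide; a constant segment
#' maps to 0.5 everywhere with a warning.
#'
#' @param plddt_segment numeric vector (length >= 2).
#' @return Values in \[0, 1\].
#' @export
pldnorm <- function(plddt_segment) {
  stopifnot(length(plddt_segment) >= 2L)
  rng <- range(plddt_segment)
  if (diff(rng) == 0) {
    warning("constant segment; pLDnorm undefined, returning 0.5")
    return(rep(0.5, length(plddt_segment)))
  }
  (plddt_segment - rng[1]) / diff(rng)
}

#' Fit structure propensity against normalised confidence
#'
#' Least-squares fit of per-residue structure propensity (e.g. helical
#' propensity from an ensemble) against pLDnorm, either as a line or as a
#' power law `y = a * x^b` (least squares in log-log space; non-positive
#' points are dropped with a warning). Pearson r of the fitted relationship
#' is reported.
#'
#' @param pldnorm_values numeric in \[0, 1\].
#' @param propensity_values numeric in \[0, 1\], same length (>= 3).
#' @param model `"line"` or `"power_law"`.
#' @return List with `model`, coefficients (`slope`/`intercept` or
#'   `a`/`b`), `r`, and `n_used`.
#' @export
fit_propensity <- function(pldnorm_values, propensity_values,
                           model = c("line", "power_law")) {
  model <- match.arg(model)
  stopifnot(length(pldnorm_values) == length(propensity_values),
            length(pldnorm_values) >= 3L)
  x <- pldnorm_values; y <- propensity_values
  if (model == "line") {
    fit <- lm(y ~ x)
    return(list(model = model, slope = unname(coef(fit)[2]),
                intercept = unname(coef(fit)[1]), r = cor(x, y),
                n_used = length(x)))
  }
  ok <- x > 0 & y > 0
  if (!all(ok)) warning(sum(!ok), " non-positive points dropped for power-law fit")
  if (sum(ok) < 3L) stop("fewer than 3 positive points for power-law fit")
  fit <- lm(log(y[ok]) ~ log(x[ok]))
  list(model = model, a = exp(unname(coef(fit)[1])), b = unname(coef(fit)[2]),
       r = cor(log(x[ok]), log(y[ok])), n_used = sum(ok))
}
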