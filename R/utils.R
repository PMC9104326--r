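# Small shared helpers. Internal only.

vec_norm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < .Machine$double.eps) stop("cannot normalise a zero-length vector")
  v / n
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so reproducible draws inside the package never disturb the
#' user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# round-half-up to integer (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

# Expand 1-based inclusive intervals into a residue membership mask.
intervals_to_mask <- function(intervals, length) {
  mask <- logical(length)
  if (is.null(intervals) || nrow(intervals) == 0L) return(mask)
  for (k in seq_len(nrow(intervals))) {
    s <- intervals$start[k]
    e <- intervals$end[k]
    if (s < 1L || e > length) {
      stop(sprintf("interval (%d, %d) outside sequence of length %d", s, e, length))
    }
    mask[s:e] <- TRUE
  }
  mask
}

# Collapse a logical membership mask into 1-based inclusive intervals.
mask_to_intervals <- function(mask) {
  if (!any(mask)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# Centred moving average; shrinks to the available window at the ends.
moving_average <- function(x, window) {
  window <- as.integer(window)
  if (window <= 1L) return(x)
  half <- window %/% 2L
  n <- length(x)
  out <- numeric(n)
  cs <- cumsum(c(0, x))
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out
}

# Adjusted Fisher-free sample skewness (the plain moment estimator m3/m2^1.5).
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}
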