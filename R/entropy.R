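# Template matrices and Chebyshev distances shared by the entropy measures.
# Templates of length m starting at positions `idx` (1-based).
entropy_templates <- function(x, m, idx) {
  out <- matrix(0, length(idx), m)
  for (k in seq_len(m)) out[, k] <- x[idx + k - 1L]
  out
}

# Chebyshev (max-coordinate) distance matrix between template rows.
cheb_dist <- function(A) {
  d <- abs(outer(A[, 1L], A[, 1L], "-"))
  if (ncol(A) > 1L)
    for (k in 2:ncol(A)) d <- pmax(d, abs(outer(A[, k], A[, k], "-")))
  d
}

check_entropy_input <- function(x, m) {
  if (length(x) < 10L * m)
    stop("entropy estimates need at least 10*m = ", 10L * m, " samples")
  if (!all(is.finite(x))) stop("input contains non-finite values")
}

#' Approximate entropy
#'
#' Regularity statistic `ApEn(m, r)`: the negative average log conditional
#' probability that runs of length `m` that match within tolerance `r` still
#' match at length `m + 1`. Matches are counted with the Chebyshev distance
#' and include self-matches, following Pincus' original estimator.
#'
#' @param x Numeric vector (length at least `10 * m`).
#' @param m Embedding (template) length; default 2.
#' @param r Tolerance as a fraction of `sd(x)`; default 0.2.
#' @return A single non-negative number; 0 for a perfectly regular signal.
#' @export
approximate_entropy <- function(x, m = 2L, r = 0.2) {
  x <- as.numeric(x); m <- as.integer(m)
  check_entropy_input(x, m)
  r_abs <- r * stats::sd(x)
  n <- length(x)
  phi <- function(mm) {
    idx <- seq_len(n - mm + 1L)
    d <- cheb_dist(entropy_templates(x, mm, idx))
    mean(log(rowSums(d <= r_abs) / length(idx)))
  }
  phi(m) - phi(m + 1L)
}

#' Sample entropy
#'
#' `SampEn(m, r) = -ln(A/B)`, where `B` counts template pairs of length `m`
#' within Chebyshev tolerance `r` and `A` the same pairs still matching at
#' length `m + 1`; self-matches are excluded and both counts use the first
#' `n - m` templates (Richman & Moorman). When no pair matches at length
#' `m + 1` the statistic is infinite; this implementation returns the
#' finite upper bound `ln(B)` with a warning rather than failing.
#'
#' @inheritParams approximate_entropy
#' @return A single non-negative number; 0 for a constant signal.
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2) {
  x <- as.numeric(x); m <- as.integer(m)
  check_entropy_input(x, m)
  r_abs <- r * stats::sd(x)
  n <- length(x)
  idx <- seq_len(n - m)
  count_pairs <- function(mm) {
    d <- cheb_dist(entropy_templates(x, mm, idx))
    (sum(d <= r_abs) - length(idx)) / 2   # exclude self, unordered pairs
  }
  B <- count_pairs(m)
  A <- count_pairs(m + 1L)
  if (B == 0) {
    warning("no template matches at length m; sample entropy undefined")
    return(NA_real_)
  }
  if (A == 0) {
    warning("no template matches at length m+1; returning upper bound ln(B)")
    return(log(B))
  }
  -log(A / B)
}

#' Fuzzy entropy
#'
#' Like sample entropy but with a soft match: baseline-removed templates
#' (each template has its own mean subtracted) contribute the exponential
#' membership `exp(-(d/r)^n_exp)` of their Chebyshev distance `d` instead of
#' a hard 0/1 count, which makes the statistic continuous in the data and
#' stable on short segments.
#'
#' @inheritParams approximate_entropy
#' @param n_exp Exponent of the membership function (default 2).
#' @return A single non-negative number.
#' @export
fuzzy_entropy <- function(x, m = 2L, r = 0.2, n_exp = 2) {
  x <- as.numeric(x); m <- as.integer(m)
  check_entropy_input(x, m)
  r_abs <- max(r * stats::sd(x), .Machine$double.eps)
  n <- length(x)
  idx <- seq_len(n - m)
  phi <- function(mm) {
    A <- entropy_templates(x, mm, idx)
    A <- A - rowMeans(A)
    d <- cheb_dist(A)
    mu <- exp(-(d / r_abs)^n_exp)
    # average pairwise membership, self-pairs excluded
    (sum(mu) - length(idx)) / (length(idx) * (length(idx) - 1L))
  }
  log(phi(m)) - log(phi(m + 1L))
}

# Lempel-Ziv 1976 parsing count (Kaspar & Schuster scan) of a binary vector.
lz76_count <- function(s) {
  n <- length(s)
  if (n == 0L) return(0L)
  if (n == 1L) return(1L)
  cn <- 1L; i <- 0L; k <- 1L; l <- 1L; k_max <- 1L
  repeat {
    if (s[i + k] != s[l + k]) {
      if (k > k_max) k_max <- k
      i <- i + 1L
      if (i == l) {
        cn <- cn + 1L
        l <- l + k_max
        if (l + 1L > n) break
        i <- 0L; k <- 1L; k_max <- 1L
      } else {
        k <- 1L
      }
    } else {
      k <- k + 1L
      if (l + k > n) {
        cn <- cn + 1L
        break
      }
    }
  }
  cn
}

#' Normalized Lempel-Ziv complexity
#'
#' Binarizes the signal at its median and parses the resulting 0/1 sequence
#' with the Lempel-Ziv 1976 production rule; the raw phrase count `c(n)` is
#' normalized by `n / log2(n)`, the asymptotic count for an equiprobable
#' random binary sequence, so values near 1 indicate disorder and values
#' near 0 strong regularity.
#'
#' @param x Numeric vector, length >= 2.
#' @return A single positive number (`2 * log2(n) / n` for a constant
#'   signal, the minimal parse of two phrases).
#' @export
lzc <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("Lempel-Ziv complexity needs at least 2 samples")
  s <- as.integer(x > stats::median(x))
  lz76_count(s) * log2(n) / n
}
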