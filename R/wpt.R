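# Orthonormal Daubechies scaling (low-pass) filters. The quadrature mirror
# high-pass is derived in wpt_filters(). Periodized convolution keeps the
# transform exactly orthonormal, so node energies sum to the signal energy.
.db_filters <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255092145, 0.22414386804185735,
          0.836516303737469, 0.48296291314469025),
  db4 = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965)
)

wpt_filters <- function(wavelet) {
  h <- .db_filters[[wavelet]]
  if (is.null(h))
    stop("unsupported wavelet '", wavelet, "'; one of: ",
         paste(names(.db_filters), collapse = ", "))
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  list(lo = h, hi = g)
}

# One periodized analysis step: x (even length) -> list(lo, hi), each half
# length. Circular indexing keeps Parseval exact.
wpt_step <- function(x, flt) {
  n <- length(x)
  half <- n %/% 2L
  L <- length(flt$lo)
  lo <- numeric(half); hi <- numeric(half)
  base <- 2L * (seq_len(half) - 1L)
  for (m in seq_len(L)) {
    idx <- (base + (m - 1L)) %% n + 1L
    lo <- lo + flt$lo[m] * x[idx]
    hi <- hi + flt$hi[m] * x[idx]
  }
  list(lo = lo, hi = hi)
}

# Frequency (sequency) position of each terminal node given the Paley
# (natural) traversal: a child of a node at frequency position p maps to
# 2p/2p+1 when p is even and swaps when p is odd (band mirroring of the
# high-pass branch).
wpt_freq_order <- function(level) {
  pos <- 0L
  for (l in seq_len(level)) {
    pos <- as.integer(unlist(lapply(pos, function(p) {
      if (p %% 2L == 0L) c(2L * p, 2L * p + 1L) else c(2L * p + 1L, 2L * p)
    })))
  }
  pos  # pos[i] = frequency index of the i-th natural-order node (0-based)
}

#' Full wavelet-packet node energies at one level
#'
#' Decomposes a signal with a `level`-deep wavelet packet tree (periodized
#' orthonormal Daubechies filters) and returns the energy -- the sum of
#' squared coefficients, equal by Parseval to the energy of the node's
#' reconstructed signal -- of every terminal node, ordered by frequency
#' band. Signals whose length is not a multiple of `2^level` are zero-padded
#' at the end, which leaves the total energy unchanged.
#'
#' @param x Numeric vector with at least `2^level` samples.
#' @param fs Sampling rate in Hz (used only for band edges).
#' @param wavelet One of `"db1"`, `"db2"`, `"db4"` (default `"db4"`).
#' @param level Decomposition depth (default 4, giving `2^4 = 16` bands of
#'   width `fs / 32`).
#' @return A list with `energies` (length `2^level`, frequency-ordered),
#'   and `band_edges`, a `2^level x 2` matrix of band lower/upper edges
#'   in Hz.
#' @seealso [extract_wpt_energy()] for the passband-restricted feature set.
#' @export
wpt_node_energies <- function(x, fs, wavelet = "db4", level = 4L) {
  x <- as.numeric(x)
  level <- as.integer(level)
  if (length(x) < 2^level)
    stop("signal shorter than 2^level = ", 2^level, " samples")
  if (!all(is.finite(x))) stop("input contains non-finite values")
  flt <- wpt_filters(wavelet)
  block <- 2L^level
  if (length(x) %% block != 0L)
    x <- c(x, numeric(block - length(x) %% block))
  nodes <- list(x)
  for (l in seq_len(level)) {
    nodes <- unlist(lapply(nodes, function(v) {
      s <- wpt_step(v, flt); list(s$lo, s$hi)
    }), recursive = FALSE)
  }
  energies_nat <- vapply(nodes, function(v) sum(v^2), numeric(1))
  ord <- wpt_freq_order(level)
  energies <- numeric(block)
  energies[ord + 1L] <- energies_nat
  width <- fs / 2 / block
  band_edges <- cbind(low = (0:(block - 1L)) * width,
                      high = (1:block) * width)
  list(energies = energies, band_edges = band_edges,
       level = level, wavelet = wavelet)
}

#' Wavelet-packet energy features within the analysis passband
#'
#' Runs a `level`-deep wavelet-packet decomposition and keeps the terminal
#' nodes whose frequency band lies entirely inside `[low_hz, high_hz]`, the
#' band-pass used in preprocessing. At `fs = 250` and `level = 4` the 16
#' bands are 7.8125 Hz wide and exactly 11 of them (7.8125--93.75 Hz) fall
#' inside the 5--100 Hz passband, giving 11 energy features per channel.
#'
#' @inheritParams wpt_node_energies
#' @param low_hz,high_hz Passband limits in Hz (defaults 5 and 100).
#' @return A list of class `mmg_wpt` with `node_energies` (named numeric
#'   vector), `band_edges` (matrix, one row per retained node), `level` and
#'   `wavelet`.
#' @examples
#' x <- sin(2 * pi * 40 * seq(0, 1, by = 1 / 250))
#' length(extract_wpt_energy(x, 250)$node_energies)  # 11
#' @export
extract_wpt_energy <- function(x, fs, wavelet = "db4", level = 4L,
                               low_hz = 5, high_hz = 100) {
  full <- wpt_node_energies(x, fs, wavelet, level)
  keep <- full$band_edges[, "low"] >= low_hz - 1e-9 &
    full$band_edges[, "high"] <= high_hz + 1e-9
  energies <- full$energies[keep]
  edges <- full$band_edges[keep, , drop = FALSE]
  names(energies) <- sprintf("wpe%02d", seq_len(sum(keep)))
  structure(list(node_energies = energies, band_edges = edges,
                 level = full$level, wavelet = wavelet),
            class = "mmg_wpt")
}
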