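#' Time-domain features of a single-channel segment
#'
#' Computes the ten time-domain descriptors in routine use for sEMG/MMG
#' pattern recognition: root mean square (RMS), unbiased variance (VAR),
#' zero crossings (ZC), waveform length (WL), slope sign changes (SSC), log
#' detector (LOG), mean absolute value (MAV), v-order, simple square
#' integral (SSI) and average amplitude change (AAC).
#'
#' ZC counts sign changes between consecutive samples whose amplitude jump
#' exceeds `zc_threshold`; SSC counts slope-sign reversals where both
#' neighbouring differences exceed `ssc_threshold` in magnitude. Both
#' dead-band thresholds default to 0 (pure sign/slope changes); counts
#' depend on them, so report them alongside results. The v-order statistic
#' is `(mean |x|^v)^(1/v)`; the default `v = 3` distinguishes it from RMS
#' (`v = 2`).
#'
#' @param x Numeric vector, length >= 3.
#' @param zc_threshold Amplitude dead-band for ZC (default 0).
#' @param ssc_threshold Slope dead-band for SSC (default 0).
#' @param v Order of the v-order statistic (default 3).
#' @return Named numeric vector of length 10 in the order
#'   `rms, var, zc, wl, ssc, log, mav, vorder, ssi, aac`.
#' @examples
#' extract_td(c(1, -1, 1, -1))
#' @export
extract_td <- function(x, zc_threshold = 0, ssc_threshold = 0, v = 3) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L) stop("time-domain features need at least 3 samples (SSC)")
  if (!all(is.finite(x))) stop("input contains non-finite values")

  d <- diff(x)
  rms <- sqrt(mean(x^2))
  zc <- sum(x[-n] * x[-1L] < 0 & abs(d) > zc_threshold)
  wl <- sum(abs(d))
  d1 <- d[-length(d)]; d2 <- d[-1L]
  ssc <- sum(d1 * d2 < 0 & abs(d1) > ssc_threshold & abs(d2) > ssc_threshold)
  ax <- pmax(abs(x), .Machine$double.eps)
  c(rms = rms,
    var = stats::var(x),
    zc = zc,
    wl = wl,
    ssc = ssc,
    log = exp(mean(log(ax))),
    mav = mean(abs(x)),
    vorder = mean(abs(x)^v)^(1 / v),
    ssi = sum(x^2),
    aac = wl / (n - 1))
}

# Welch power spectral density: Hann window, 50% overlap.
# Returns freqs in Hz and one-sided power estimates.
welch_psd <- function(x, fs, seg_len = min(256L, length(x))) {
  n <- length(x)
  seg_len <- min(as.integer(seg_len), n)
  hop <- max(1L, seg_len %/% 2L)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(seg_len - 1)) / seg_len)  # periodic Hann
  starts <- seq(1L, n - seg_len + 1L, by = hop)
  acc <- numeric(seg_len)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)] * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  p <- acc / (length(starts) * sum(w^2) * fs)
  half <- seg_len %/% 2L
  freq <- (0:half) * fs / seg_len
  pow <- p[1:(half + 1L)]
  # fold the negative-frequency half into the one-sided estimate
  if (seg_len %% 2L == 0L) {
    if (half >= 2L) pow[2:half] <- 2 * pow[2:half]
  } else if (half >= 1L) pow[2:(half + 1L)] <- 2 * pow[2:(half + 1L)]
  list(freq = freq, power = pow)
}

#' Frequency-domain features of a single-channel segment
#'
#' Estimates the power spectral density by Welch's method (Hann window,
#' segments of `min(256, n)` samples, 50% overlap) and reduces it to the two
#' spectral summaries standard in muscle-signal work: mean power frequency
#' (MPF), the power-weighted mean frequency, and median frequency (MF), the
#' smallest frequency at which cumulative power reaches half the total.
#'
#' @param x Numeric vector, length >= 16.
#' @param fs Sampling rate in Hz.
#' @return Named numeric vector `c(mpf, mf)` in Hz.
#' @export
extract_fd <- function(x, fs) {
  x <- as.numeric(x)
  if (length(x) < 16L) stop("frequency-domain features need at least 16 samples")
  psd <- welch_psd(x, fs)
  tot <- sum(psd$power)
  if (tot <= 0) stop("degenerate input: zero-power signal")
  mpf <- sum(psd$freq * psd$power) / tot
  mf <- psd$freq[which(cumsum(psd$power) >= tot / 2)[1L]]
  c(mpf = mpf, mf = mf)
}
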