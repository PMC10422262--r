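#' Zero-phase band-pass filtering of a multichannel recording
#'
#' Applies a Butterworth band-pass filter forward and backward
#' (`signal::filtfilt`) to every channel, so the output has zero phase lag
#' and movement onsets are not shifted in time. MMG carries its information
#' below 100 Hz, and frequencies below about 5 Hz are dominated by motion
#' artifact, hence the default 5--100 Hz band used throughout the package.
#'
#' @param rec An [mmg_recording()].
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < fs/2`.
#' @param order Butterworth prototype order (default 4).
#' @return A filtered `mmg_recording` of the same shape.
#' @examples
#' t <- seq(0, 2, by = 1 / 250)
#' rec <- mmg_recording(cbind(sin(2 * pi * 50 * t)), fs = 250)
#' filt <- bandpass_filter(rec)
#' @export
bandpass_filter <- function(rec, low_hz = 5, high_hz = 100, order = 4L) {
  stopifnot(is_recording(rec))
  fs <- rec$fs
  if (!(low_hz > 0 && low_hz < high_hz))
    stop("band edges must satisfy 0 < low_hz < high_hz")
  if (high_hz >= fs / 2)
    stop("'high_hz' must be below the Nyquist frequency fs/2 = ", fs / 2)
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  out <- apply(rec$data, 2L, function(x) signal::filtfilt(bf, x))
  out <- matrix(out, nrow = nrow(rec$data))
  mmg_recording(out, fs, rec$channel_names)
}

#' Short-time energy of a multichannel recording
#'
#' Slides a window of `window_len` samples with step `hop` and computes, per
#' window, the mean squared amplitude pooled over all channels. This is the
#' activity trace used to locate movement bursts.
#'
#' @param rec An [mmg_recording()].
#' @param window_len Window length in samples (default 32, i.e. 128 ms at
#'   250 Hz).
#' @param hop Hop between window starts in samples (default 16, 50% overlap).
#' @return A list of class `mmg_energy` with `values` (one non-negative
#'   energy per window), `window_len` and `hop`.
#' @export
short_time_energy <- function(rec, window_len = 32L, hop = 16L) {
  stopifnot(is_recording(rec))
  n <- nrow(rec$data)
  window_len <- as.integer(window_len); hop <- as.integer(hop)
  if (window_len < 1L || window_len > n)
    stop("'window_len' must be between 1 and the number of samples (", n, ")")
  if (hop < 1L) stop("'hop' must be >= 1")
  n_win <- (n - window_len) %/% hop + 1L
  sq <- rec$data^2
  # cumulative sum per channel -> O(1) window sums
  cs <- rbind(0, apply(sq, 2L, cumsum))
  starts <- (seq_len(n_win) - 1L) * hop + 1L
  win_sums <- cs[starts + window_len, , drop = FALSE] - cs[starts, , drop = FALSE]
  values <- rowMeans(win_sums) / window_len
  structure(list(values = values, window_len = window_len, hop = hop),
            class = "mmg_energy")
}

#' Segment movement bursts by thresholded short-time energy
#'
#' Windows whose pooled energy exceeds `threshold_frac` times the maximum
#' windowed energy are marked active; contiguous active runs are expanded to
#' sample coordinates, runs separated by less than `merge_gap_s` are merged,
#' and segments shorter than `min_duration_s` are dropped. The threshold is
#' relative, so segmentation is invariant to the overall gain of the
#' recording.
#'
#' @inheritParams short_time_energy
#' @param threshold_frac Relative energy threshold in (0, 1); default 0.1.
#' @param min_duration_s Minimum segment duration in seconds (default 0.3).
#' @param merge_gap_s Gaps shorter than this (seconds) are bridged
#'   (default 0.2).
#' @return A list of segments, each a list with 0-based half-open sample
#'   coordinates `start`, `end` and the `data` excerpt. A silent recording
#'   yields an empty list.
#' @export
segment_movements <- function(rec, window_len = 32L, hop = 16L,
                              threshold_frac = 0.1, min_duration_s = 0.3,
                              merge_gap_s = 0.2) {
  stopifnot(is_recording(rec))
  if (!(threshold_frac > 0 && threshold_frac < 1))
    stop("'threshold_frac' must lie in (0, 1)")
  en <- short_time_energy(rec, window_len, hop)
  emax <- max(en$values)
  if (emax <= 0) return(list())
  active <- en$values > threshold_frac * emax
  if (!any(active)) return(list())

  r <- rle(active)
  ends_w <- cumsum(r$lengths)
  starts_w <- ends_w - r$lengths + 1L
  runs <- cbind(starts_w[r$values], ends_w[r$values])   # window indices

  n <- nrow(rec$data)
  # window k covers samples [(k-1)*hop, (k-1)*hop + window_len) 0-based
  seg <- cbind((runs[, 1L] - 1L) * hop,
               pmin((runs[, 2L] - 1L) * hop + window_len, n))

  merge_gap <- merge_gap_s * rec$fs
  merged <- seg[1L, , drop = FALSE]
  if (nrow(seg) > 1L) {
    for (i in 2:nrow(seg)) {
      last <- nrow(merged)
      if (seg[i, 1L] - merged[last, 2L] < merge_gap)
        merged[last, 2L] <- seg[i, 2L]
      else
        merged <- rbind(merged, seg[i, , drop = FALSE])
    }
  }
  keep <- (merged[, 2L] - merged[, 1L]) >= min_duration_s * rec$fs
  merged <- merged[keep, , drop = FALSE]
  lapply(seq_len(nrow(merged)), function(i) {
    s <- merged[i, 1L]; e <- merged[i, 2L]
    list(start = as.integer(s), end = as.integer(e),
         data = rec$data[(s + 1L):e, , drop = FALSE])
  })
}
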