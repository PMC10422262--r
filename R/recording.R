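#' Multichannel MMG recording
#'
#' Container for a multichannel mechanomyography (MMG) recording: a numeric
#' matrix with one column per sensor channel, a sampling rate, and channel
#' names (by convention the muscle sites the accelerometers were placed on).
#'
#' @param data Numeric matrix or data frame, samples in rows, channels in
#'   columns. All values must be finite.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_names Optional character vector of channel names; defaults
#'   to `"ch1"`, `"ch2"`, ... matching the number of columns.
#'
#' @return An object of class `mmg_recording`: a list with elements `data`
#'   (numeric matrix), `fs` and `channel_names`.
#' @examples
#' rec <- mmg_recording(matrix(rnorm(500 * 2), ncol = 2), fs = 250)
#' rec
#' @export
mmg_recording <- function(data, fs, channel_names = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 1L || ncol(data) < 1L)
    stop("recording must have at least one sample and one channel")
  if (!all(is.finite(data)))
    stop("recording contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a positive finite scalar")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(ncol(data)))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != ncol(data))
    stop("'channel_names' length must match the number of channels")
  colnames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names),
            class = "mmg_recording")
}

#' @export
print.mmg_recording <- function(x, ...) {
  cat(sprintf("<mmg_recording: %d samples x %d channels @ %g Hz (%.2f s)>\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$data) / x$fs))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.mmg_recording <- function(x) dim(x$data)

is_recording <- function(x) inherits(x, "mmg_recording")

#' Labelled movement segment
#'
#' One movement's multichannel excerpt together with its class label and,
#' optionally, the posture condition it was recorded in.
#'
#' @param data Numeric matrix (samples x channels) holding the excerpt.
#' @param fs Sampling rate in Hz.
#' @param label Class label (e.g. `"KE"`, `"KF"`, `"AD"`, `"AP"`).
#' @param start,end Sample coordinates of the excerpt in the source
#'   recording, 0-based half-open `[start, end)`; optional.
#' @param condition Optional posture tag, e.g. `"sitting"` or `"standing"`.
#'
#' @return An object of class `mmg_segment`.
#' @export
mmg_segment <- function(data, fs, label, start = 0L, end = nrow(data),
                        condition = NA_character_) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  stopifnot(start >= 0, end > start)
  structure(list(data = data, fs = fs, label = as.character(label),
                 start = as.integer(start), end = as.integer(end),
                 condition = as.character(condition)),
            class = "mmg_segment")
}

#' @export
print.mmg_segment <- function(x, ...) {
  cat(sprintf("<mmg_segment '%s' [%d, %d): %d samples x %d channels @ %g Hz>\n",
              x$label, x$start, x$end, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}
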