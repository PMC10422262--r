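#' Synthetic MMG generator configuration
#'
#' Parameters of the seeded generator that emulates the structure of a
#' lower-limb MMG acquisition session: four movement classes (knee
#' extension/flexion, ankle dorsiflexion/plantarflexion), four sensor
#' channels at 250 Hz, 100 repetitions per class. Each class is given a
#' signature in two ways that mirror how real movements differ across
#' muscle sites: a per-channel amplitude gain pattern and a per-class
#' spectral centroid of the band-limited (5--100 Hz) burst noise. A burst
#' is embedded between rest periods whose noise floor is a small fraction
#' of the burst amplitude, so the relative short-time-energy threshold
#' segments it cleanly.
#'
#' @param n_classes,n_channels Numbers of movement classes and channels.
#' @param fs Sampling rate in Hz.
#' @param reps_per_class Repetitions of each movement class.
#' @param burst_duration_s,rest_duration_s Burst length and rest padding on
#'   each side, in seconds.
#' @param gains `n_classes x n_channels` non-negative amplitude matrix;
#'   the default pairs the classes (knee vs ankle) with swapped dominant
#'   channels within a pair.
#' @param centroids_hz Per-class spectral centroid of the burst noise, all
#'   inside (5, 100) Hz.
#' @param bandwidth_hz Half-width of the class spectral band.
#' @param noise_sd Overall burst amplitude scale.
#' @param gain_jitter_sd Trial-to-trial log-normal jitter of every channel
#'   gain (SD on the log scale); emulates the large repetition variability
#'   of real muscle recordings.
#' @param centroid_jitter_hz Trial-to-trial Gaussian jitter of the class
#'   spectral centroid, in Hz.
#' @param rest_noise_frac Rest-floor standard deviation as a fraction of
#'   `noise_sd` (default 0.05).
#' @param ramp_s Raised-cosine onset/offset duration of the burst envelope.
#' @param class_labels Class label strings.
#' @param condition Posture tag attached to generated segments.
#' @param seed Integer seed.
#' @return A list of class `mmg_gen_config`.
#' @export
generator_config <- function(n_classes = 4L, n_channels = 4L, fs = 250,
                             reps_per_class = 100L,
                             burst_duration_s = 1.2, rest_duration_s = 0.8,
                             gains = NULL,
                             centroids_hz = c(30, 36, 42, 48),
                             bandwidth_hz = 15,
                             noise_sd = 1,
                             gain_jitter_sd = 0.3, centroid_jitter_hz = 4,
                             rest_noise_frac = 0.05,
                             ramp_s = 0.15,
                             class_labels = c("KE", "KF", "AD", "AP"),
                             condition = "sitting", seed = 1L) {
  n_classes <- as.integer(n_classes); n_channels <- as.integer(n_channels)
  if (is.null(gains)) {
    gains <- matrix(0.5, n_classes, n_channels)
    for (cl in seq_len(n_classes)) {
      dom <- ((cl - 1L) %% n_channels) + 1L
      sub <- (cl %% n_channels) + 1L
      gains[cl, dom] <- 1.0
      gains[cl, sub] <- 0.75
    }
  }
  gains <- as.matrix(gains)
  stopifnot(nrow(gains) == n_classes, ncol(gains) == n_channels,
            all(gains >= 0), length(centroids_hz) == n_classes,
            all(centroids_hz > 5), all(centroids_hz < 100),
            fs > 2 * max(centroids_hz + bandwidth_hz))
  class_labels <- rep_len(as.character(class_labels), n_classes)
  structure(list(n_classes = n_classes, n_channels = n_channels, fs = fs,
                 reps_per_class = as.integer(reps_per_class),
                 burst_duration_s = burst_duration_s,
                 rest_duration_s = rest_duration_s, gains = gains,
                 centroids_hz = centroids_hz, bandwidth_hz = bandwidth_hz,
                 noise_sd = noise_sd, gain_jitter_sd = gain_jitter_sd,
                 centroid_jitter_hz = centroid_jitter_hz,
                 rest_noise_frac = rest_noise_frac,
                 ramp_s = ramp_s, class_labels = class_labels,
                 condition = condition, seed = as.integer(seed)),
            class = "mmg_gen_config")
}

raised_cosine_envelope <- function(n_burst, n_ramp) {
  env <- rep(1, n_burst)
  if (n_ramp > 0L && 2L * n_ramp <= n_burst) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(n_ramp) / n_ramp))
    env[seq_len(n_ramp)] <- ramp
    env[(n_burst - n_ramp + 1L):n_burst] <- rev(ramp)
  }
  env
}

#' Generate one synthetic movement recording
#'
#' Produces rest / burst / rest: class-filtered Gaussian noise (band-pass
#' around the class spectral centroid, clipped to 5--100 Hz) scaled per
#' channel by the class gain row and shaped by a raised-cosine
#' onset--plateau--offset envelope, on top of a low-amplitude band-limited
#' rest noise floor. Draws from R's current random stream; seed it (or use
#' [generate_dataset()]) for reproducibility.
#'
#' @param class_id Class index in `1..n_classes`.
#' @param cfg A [generator_config()].
#' @return An [mmg_recording()].
#' @export
generate_movement <- function(class_id, cfg) {
  stopifnot(inherits(cfg, "mmg_gen_config"),
            class_id >= 1L, class_id <= cfg$n_classes)
  fs <- cfg$fs
  n_rest <- round(cfg$rest_duration_s * fs)
  n_burst <- round(cfg$burst_duration_s * fs)
  n <- 2L * n_rest + n_burst
  centroid <- cfg$centroids_hz[class_id] +
    stats::rnorm(1L, 0, cfg$centroid_jitter_hz)
  centroid <- min(max(centroid, 5 + cfg$bandwidth_hz / 2), 95)
  lo <- max(5, centroid - cfg$bandwidth_hz)
  hi <- min(100, centroid + cfg$bandwidth_hz)
  bf_class <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  bf_rest <- signal::butter(4, c(5, 100) / (fs / 2), type = "pass")
  env <- raised_cosine_envelope(n_burst, round(cfg$ramp_s * fs))
  burst_idx <- (n_rest + 1L):(n_rest + n_burst)

  data <- matrix(0, n, cfg$n_channels)
  jitter <- exp(stats::rnorm(cfg$n_channels, 0, cfg$gain_jitter_sd))
  for (ch in seq_len(cfg$n_channels)) {
    core <- signal::filtfilt(bf_class, stats::rnorm(n_burst))
    rms <- sqrt(mean(core^2))
    if (rms > 0) core <- core / rms
    x <- signal::filtfilt(bf_rest, stats::rnorm(n)) *
      cfg$rest_noise_frac * cfg$noise_sd
    x[burst_idx] <- x[burst_idx] +
      core * env * cfg$gains[class_id, ch] * jitter[ch] * cfg$noise_sd
    data[, ch] <- x
  }
  mmg_recording(data, fs, paste0("ch", seq_len(cfg$n_channels)))
}

#' Generate a labelled synthetic MMG dataset
#'
#' Generates `reps_per_class` movements per class and pushes every
#' recording through the real preprocessing path -- band-pass filtering and
#' short-time-energy segmentation -- so the returned segments mirror what
#' the pipeline would produce from raw recordings. Any recording that does
#' not segment into exactly one burst raises an error: a disagreement
#' between generator and segmenter is a bug signal, not something to paper
#' over.
#'
#' @param cfg A [generator_config()].
#' @param low_hz,high_hz Preprocessing band (defaults 5 and 100 Hz).
#' @param ... Further arguments passed to [segment_movements()].
#' @return List of `cfg$n_classes * cfg$reps_per_class` [mmg_segment()]
#'   objects with balanced labels.
#' @export
generate_dataset <- function(cfg = generator_config(), low_hz = 5,
                             high_hz = 100, ...) {
  set.seed(cfg$seed)
  segments <- vector("list", cfg$n_classes * cfg$reps_per_class)
  k <- 0L
  for (cl in seq_len(cfg$n_classes)) {
    for (rep in seq_len(cfg$reps_per_class)) {
      rec <- generate_movement(cl, cfg)
      filt <- bandpass_filter(rec, low_hz, high_hz)
      segs <- segment_movements(filt, ...)
      if (length(segs) != 1L)
        stop("generator/segmenter disagreement: class ", cl, " repetition ",
             rep, " segmented into ", length(segs), " bursts (expected 1)")
      k <- k + 1L
      segments[[k]] <- mmg_segment(segs[[1L]]$data, cfg$fs,
                                   cfg$class_labels[cl],
                                   segs[[1L]]$start, segs[[1L]]$end,
                                   cfg$condition)
    }
  }
  segments
}

#' Planted-feature dataset for selector validation
#'
#' Abstract dataset with `k_informative` columns whose class means are
#' shifted (per column, per class, shift scale `effect_size`) and
#' `p - k_informative` pure-noise columns. Used to check that the wrapper
#' recovers the informative set.
#'
#' @param n Number of rows (balanced over classes).
#' @param p Number of feature columns.
#' @param k_informative Number of informative columns.
#' @param effect_size Standard deviation of the per-class mean shifts.
#' @param n_classes Number of classes (default 4).
#' @param seed Integer seed.
#' @return List of class `mmg_planted` with `X`, `y` and
#'   `informative_indices`.
#' @export
generate_planted <- function(n, p, k_informative, effect_size,
                             n_classes = 4L, seed = 1L) {
  stopifnot(k_informative <= p, n >= n_classes)
  set.seed(seed)
  y <- rep_len(paste0("C", seq_len(n_classes)), n)
  X <- matrix(stats::rnorm(n * p), n, p)
  informative <- sort(sample.int(p, k_informative))
  for (j in informative) {
    shifts <- stats::rnorm(n_classes, 0, effect_size)
    X[, j] <- X[, j] + shifts[match(y, paste0("C", seq_len(n_classes)))]
  }
  colnames(X) <- sprintf("f%02d", seq_len(p))
  structure(list(X = X, y = y, informative_indices = informative),
            class = "mmg_planted")
}

#' Wrap a planted dataset as a feature matrix
#'
#' @param pd An `mmg_planted` object from [generate_planted()].
#' @return An `mmg_features` object usable by [select_features()].
#' @export
planted_features <- function(pd) {
  stopifnot(inherits(pd, "mmg_planted"))
  structure(list(X = pd$X, y = pd$y, names = colnames(pd$X)),
            class = "mmg_features")
}
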