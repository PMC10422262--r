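# Shared fixtures, built in code at test time.

sine_recording <- function(freq, fs = 250, dur = 4, n_channels = 1L,
                           amp = 1) {
  t <- seq(0, dur, by = 1 / fs)
  mmg_recording(matrix(rep(amp * sin(2 * pi * freq * t), n_channels),
                       ncol = n_channels), fs)
}

# Silence + bursts at known sample positions (white noise scaled by `amp`).
burst_recording <- function(burst_starts, burst_len, total_len, fs = 250,
                            n_channels = 2L, amp = 1, seed = 42) {
  set.seed(seed)
  data <- matrix(0, total_len, n_channels)
  for (s in burst_starts)
    data[(s + 1):(s + burst_len), ] <- amp *
      matrix(rnorm(burst_len * n_channels), burst_len)
  mmg_recording(data, fs)
}

# Small labelled segment set without the generator (for fast feature tests).
toy_segments <- function(n_per_class = 3L, n_channels = 2L, len = 250L,
                         fs = 250, seed = 7) {
  set.seed(seed)
  out <- list()
  for (cl in c("A", "B")) {
    freq <- if (cl == "A") 20 else 60
    for (i in seq_len(n_per_class)) {
      t <- (0:(len - 1)) / fs
      data <- sapply(seq_len(n_channels), function(ch)
        sin(2 * pi * freq * t + runif(1, 0, 2 * pi)) + 0.2 * rnorm(len))
      out[[length(out) + 1L]] <- mmg_segment(data, fs, cl)
    }
  }
  out
}

# Two well-separated Gaussian classes wrapped as a feature matrix.
separable_features <- function(n = 80L, p = 4L, shift = 6, seed = 11) {
  set.seed(seed)
  y <- rep(c("A", "B"), length.out = n)
  X <- matrix(rnorm(n * p), n, p)
  X[y == "B", 1L] <- X[y == "B", 1L] + shift
  colnames(X) <- paste0("f", seq_len(p))
  structure(list(X = X, y = y, names = colnames(X)), class = "mmg_features")
}

# The full-size default synthetic dataset and its 108-column feature matrix
# are expensive; build them once per test run.
.fixture_cache <- new.env(parent = emptyenv())

default_dataset <- function() {
  if (is.null(.fixture_cache$segments))
    .fixture_cache$segments <- generate_dataset(generator_config(seed = 1))
  .fixture_cache$segments
}

default_features <- function() {
  if (is.null(.fixture_cache$fm))
    .fixture_cache$fm <- build_feature_matrix(default_dataset())
  .fixture_cache$fm
}
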