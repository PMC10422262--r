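#' Feature-extraction parameters
#'
#' Bundles the tunable parameters of the four feature families with the
#' defaults used throughout the package: zero dead-bands for the ZC/SSC
#' counts, `v = 3` for the v-order statistic, a db4 wavelet at level 4 with
#' the 5--100 Hz passband for the wavelet-packet energies, and the
#' field-standard entropy settings `m = 2`, `r = 0.2 * sd`, fuzzy exponent 2.
#'
#' @param zc_threshold,ssc_threshold Dead-bands for the ZC/SSC counts.
#' @param v Order of the v-order time-domain statistic.
#' @param wavelet,level Wavelet-packet family and depth.
#' @param wpt_low_hz,wpt_high_hz Passband restricting the retained nodes.
#' @param m,r,n_exp Entropy template length, tolerance (fraction of SD) and
#'   fuzzy membership exponent.
#' @return A named list of parameters.
#' @export
feature_params <- function(zc_threshold = 0, ssc_threshold = 0, v = 3,
                           wavelet = "db4", level = 4L,
                           wpt_low_hz = 5, wpt_high_hz = 100,
                           m = 2L, r = 0.2, n_exp = 2) {
  list(zc_threshold = zc_threshold, ssc_threshold = ssc_threshold, v = v,
       wavelet = wavelet, level = level,
       wpt_low_hz = wpt_low_hz, wpt_high_hz = wpt_high_hz,
       m = m, r = r, n_exp = n_exp)
}

#' @rdname build_feature_matrix
#' @export
feature_families <- function() c("TD", "FD", "WE", "NLD")

extract_family <- function(x, fs, family, params) {
  switch(family,
    TD = extract_td(x, params$zc_threshold, params$ssc_threshold, params$v),
    FD = extract_fd(x, fs),
    WE = extract_wpt_energy(x, fs, params$wavelet, params$level,
                            params$wpt_low_hz, params$wpt_high_hz)$node_energies,
    NLD = c(aen = approximate_entropy(x, params$m, params$r),
            sen = sample_entropy(x, params$m, params$r),
            fen = fuzzy_entropy(x, params$m, params$r, params$n_exp),
            lzc = lzc(x)),
    stop("unknown feature family '", family, "'")
  )
}

#' Assemble a feature matrix from labelled segments
#'
#' Extracts the requested feature families from the requested channels of
#' every segment and stacks them into a segments-by-features matrix with a
#' deterministic column order: channel-major, families in the fixed order
#' TD, FD, WE, NLD, features in their family order. Column names follow the
#' pattern `"ch<c>:<family>:<feature>"`. Family sizes are TD = 10, FD = 2,
#' WE = 11, NLD = 4, so all four families over four channels give
#' `4 x 27 = 108` columns.
#'
#' No per-column normalization is applied here: z-scoring is done inside
#' cross-validation from training-fold statistics only (see
#' [evaluate_mask()]), which avoids information leaking from test folds.
#'
#' @param segments List of [mmg_segment()] objects.
#' @param channels Integer indices (or names) of the channels to use;
#'   default all channels of the first segment.
#' @param families Subset of `c("TD", "FD", "WE", "NLD")`; default all.
#' @param params Parameter list from [feature_params()].
#' @return An object of class `mmg_features`: list with `X` (numeric
#'   matrix), `y` (character label vector) and `names` (column names).
#' @export
build_feature_matrix <- function(segments, channels = NULL,
                                 families = feature_families(),
                                 params = feature_params()) {
  if (length(segments) == 0L) stop("'segments' is empty")
  families <- match.arg(families, feature_families(), several.ok = TRUE)
  families <- feature_families()[feature_families() %in% families]
  n_ch <- ncol(segments[[1L]]$data)
  ch_names <- colnames(segments[[1L]]$data)
  if (is.null(channels)) channels <- seq_len(n_ch)
  if (is.character(channels)) channels <- match(channels, ch_names)
  channels <- as.integer(channels)
  if (anyNA(channels) || any(channels < 1L | channels > n_ch))
    stop("'channels' must be a subset of the segments' channels")

  rows <- lapply(seq_along(segments), function(i) {
    seg <- segments[[i]]
    vals <- unlist(lapply(channels, function(ch) {
      unlist(lapply(families, function(fam) {
        v <- tryCatch(
          extract_family(seg$data[, ch], seg$fs, fam, params),
          error = function(e) stop("segment ", i, " (label '", seg$label,
                                   "'), channel ", ch, ", family ", fam,
                                   ": ", conditionMessage(e), call. = FALSE))
        names(v) <- paste0("ch", ch, ":", fam, ":", names(v))
        v
      }))
    }))
    bad <- !is.finite(vals)
    if (any(bad))
      stop("segment ", i, " (label '", seg$label, "') produced non-finite ",
           "feature(s): ", paste(names(vals)[bad], collapse = ", "))
    vals
  })
  X <- do.call(rbind, rows)
  y <- vapply(segments, function(s) s$label, character(1))
  structure(list(X = X, y = y, names = colnames(X)), class = "mmg_features")
}

#' @export
print.mmg_features <- function(x, ...) {
  cat(sprintf("<mmg_features: %d segments x %d features>\n",
              nrow(x$X), ncol(x$X)))
  tab <- table(x$y)
  cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab),
                          collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.mmg_features <- function(x) dim(x$X)
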