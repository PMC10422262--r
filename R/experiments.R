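#' The seven benchmark feature-set combinations
#'
#' The family subsets compared in the feature-set experiment: TD alone,
#' TD+FD, TD+WE, TD+FD+WE, TD+NLD, TD+FD+NLD, and FD+WE (the only set
#' without time-domain features).
#'
#' @return Named list of character vectors of family names.
#' @export
default_feature_sets <- function() {
  list(
    "TD"        = c("TD"),
    "TD+FD"     = c("TD", "FD"),
    "TD+WE"     = c("TD", "WE"),
    "TD+FD+WE"  = c("TD", "FD", "WE"),
    "TD+NLD"    = c("TD", "NLD"),
    "TD+FD+NLD" = c("TD", "FD", "NLD"),
    "FD+WE"     = c("FD", "WE")
  )
}

opt_cfg_for <- function(template, n_feat, seed) {
  optimizer_config(dim = n_feat, lb = 0, ub = 1,
                   pop_size = template$pop_size, max_iter = template$max_iter,
                   seed = seed, p1 = template$p1, p2 = template$p2,
                   pp = template$pp, alpha_csa = template$alpha_csa,
                   c1 = template$c1, c2 = template$c2, p_w = template$p_w,
                   a_min = template$a_min, f_attract = template$f_attract,
                   l_scale = template$l_scale, c_max = template$c_max,
                   c_min = template$c_min)
}

#' Compare wrapper selection across feature-set combinations
#'
#' Builds one feature matrix per family subset from the same segments and
#' runs the wrapper once per subset, algorithm and seed, reporting mean
#' cross-validated accuracy, selected-feature count and wall time. Wall
#' times are hardware-dependent and reported for orientation only.
#'
#' @param segments List of [mmg_segment()] objects.
#' @param feature_sets Named list of family subsets; default
#'   [default_feature_sets()].
#' @param algorithms Subset of `c("csa", "goa")`.
#' @param threshold,tf_name Binarization settings (see [binarize()]).
#' @param opt_cfg Optimizer settings template (dimension is replaced per
#'   feature set; its `seed` is replaced by `seeds`).
#' @param cv A [cv_config()].
#' @param seeds Integer vector of wrapper seeds.
#' @param channels Channel subset passed to [build_feature_matrix()].
#' @param params Feature parameters ([feature_params()]).
#' @return Data frame with one row per feature set x algorithm x seed:
#'   `feature_set, algorithm, seed, n_features, mean_acc, mean_R,
#'   elapsed_s`.
#' @export
run_feature_set_comparison <- function(segments,
                                       feature_sets = default_feature_sets(),
                                       algorithms = c("csa", "goa"),
                                       threshold = 0.5, tf_name = "S1",
                                       opt_cfg = optimizer_config(dim = 1),
                                       cv = cv_config(), seeds = 1L,
                                       channels = NULL,
                                       params = feature_params()) {
  algorithms <- match.arg(algorithms, c("csa", "goa"), several.ok = TRUE)
  rows <- list()
  for (fs_name in names(feature_sets)) {
    fm <- build_feature_matrix(segments, channels = channels,
                               families = feature_sets[[fs_name]],
                               params = params)
    for (alg in algorithms) {
      for (sd in seeds) {
        cfg <- opt_cfg_for(opt_cfg, ncol(fm$X), sd)
        el <- system.time(
          fit <- select_features(fm, alg, threshold, tf_name, cfg, cv)
        )[["elapsed"]]
        rows[[length(rows) + 1L]] <- data.frame(
          feature_set = fs_name, algorithm = alg, seed = sd,
          n_features = ncol(fm$X), mean_acc = fit$mean_acc,
          mean_R = fit$mean_R, elapsed_s = el)
      }
    }
  }
  do.call(rbind, rows)
}

#' Compare wrapper selection across channel combinations
#'
#' Enumerates every `subset_size`-channel combination plus the full channel
#' set and runs the wrapper on each, mirroring the question of which muscle
#' sites carry the class information.
#'
#' @inheritParams run_feature_set_comparison
#' @param families Feature families used for every combination.
#' @param subset_size Size of the channel subsets (default 3).
#' @return Data frame with one row per channel subset x algorithm x seed.
#' @export
run_channel_combinations <- function(segments,
                                     families = feature_families(),
                                     algorithms = c("csa", "goa"),
                                     threshold = 0.5, tf_name = "S1",
                                     opt_cfg = optimizer_config(dim = 1),
                                     cv = cv_config(), seeds = 1L,
                                     subset_size = 3L,
                                     params = feature_params()) {
  algorithms <- match.arg(algorithms, c("csa", "goa"), several.ok = TRUE)
  n_ch <- ncol(segments[[1L]]$data)
  combos <- utils::combn(n_ch, min(subset_size, n_ch), simplify = FALSE)
  if (subset_size < n_ch) combos <- c(combos, list(seq_len(n_ch)))
  rows <- list()
  for (ch in combos) {
    fm <- build_feature_matrix(segments, channels = ch,
                               families = families, params = params)
    label <- paste(ch, collapse = "+")
    for (alg in algorithms) {
      for (sd in seeds) {
        cfg <- opt_cfg_for(opt_cfg, ncol(fm$X), sd)
        fit <- select_features(fm, alg, threshold, tf_name, cfg, cv)
        rows[[length(rows) + 1L]] <- data.frame(
          channels = label, n_channels = length(ch), algorithm = alg,
          seed = sd, mean_acc = fit$mean_acc, mean_R = fit$mean_R)
      }
    }
  }
  do.call(rbind, rows)
}

#' Sweep the binarization threshold
#'
#' Runs the wrapper over a grid of thresholds `T` for each algorithm and
#' seed, recording accuracy, selected-feature count and per-class
#' recognition rates -- the experiment that exposes how the two optimizers
#' respond to increasing selection pressure.
#'
#' @inheritParams run_feature_set_comparison
#' @param features An `mmg_features` object (built once; the sweep reuses
#'   it for every run).
#' @param thresholds Grid of `T` values in (0, 1); default
#'   `seq(0.3, 0.6, by = 0.05)`.
#' @return Data frame with one row per threshold x algorithm x seed:
#'   `threshold, algorithm, seed, mean_acc, R`, plus one
#'   `rate_<class>` column per class.
#' @export
run_threshold_sweep <- function(features,
                                thresholds = seq(0.3, 0.6, by = 0.05),
                                algorithms = c("csa", "goa"),
                                tf_name = "S1",
                                opt_cfg = optimizer_config(dim = 1),
                                cv = cv_config(), seeds = 1L) {
  stopifnot(all(thresholds > 0), all(thresholds < 1))
  algorithms <- match.arg(algorithms, c("csa", "goa"), several.ok = TRUE)
  rows <- list()
  for (alg in algorithms) {
    for (sd in seeds) {
      for (tt in thresholds) {
        cfg <- opt_cfg_for(opt_cfg, ncol(features$X), sd)
        fit <- select_features(features, alg, tt, tf_name, cfg, cv)
        row <- data.frame(threshold = tt, algorithm = alg, seed = sd,
                          mean_acc = fit$mean_acc, R = fit$mask$R)
        rates <- as.list(fit$class_rates)
        names(rates) <- paste0("rate_", names(fit$class_rates))
        rows[[length(rows) + 1L]] <- cbind(row, as.data.frame(rates))
      }
    }
  }
  do.call(rbind, rows)
}

#' Aggregate a threshold sweep over seeds
#'
#' @param sweep Data frame from [run_threshold_sweep()].
#' @return Data frame of per-threshold, per-algorithm means and standard
#'   deviations of accuracy and selected-feature count.
#' @export
summarize_sweep <- function(sweep) {
  out <- stats::aggregate(cbind(mean_acc, R) ~ threshold + algorithm,
                          data = sweep, FUN = mean)
  sds <- stats::aggregate(cbind(mean_acc, R) ~ threshold + algorithm,
                          data = sweep, FUN = stats::sd)
  names(out)[3:4] <- c("acc_mean", "R_mean")
  out$acc_sd <- sds$mean_acc
  out$R_sd <- sds$R
  out[order(out$algorithm, out$threshold), ]
}
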