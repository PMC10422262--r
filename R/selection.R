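#' Transfer functions mapping optimizer coordinates to [0, 1]
#'
#' The S-family are sigmoids of increasing/decreasing steepness
#' (`S1 = 1/(1+e^-x)`, `S2 = 1/(1+e^-2x)`, `S3 = 1/(1+e^-x/2)`); the
#' V-family use the absolute value of tanh-like maps (`V1 = |tanh(x)|`,
#' `V2 = |x/sqrt(1+x^2)|`) so that their output lies in `[0, 1]` and can be
#' compared with a threshold there. `S1` is the default used for feature
#' selection.
#'
#' @param name One of `"S1"`, `"S2"`, `"S3"`, `"V1"`, `"V2"`.
#' @param x Numeric vector of optimizer coordinates.
#' @return Numeric vector in `[0, 1]`, same length as `x`.
#' @export
transfer <- function(name, x) {
  switch(name,
    S1 = 1 / (1 + exp(-x)),
    S2 = 1 / (1 + exp(-2 * x)),
    S3 = 1 / (1 + exp(-x / 2)),
    V1 = abs(tanh(x)),
    V2 = abs(x / sqrt(1 + x^2)),
    stop("unknown transfer function '", name, "'")
  )
}

#' Decode a continuous position into a feature-selection mask
#'
#' Each coordinate is passed through the transfer function and the feature
#' is selected iff the transformed value is strictly larger than the
#' threshold `T`. An all-zero mask is repaired by selecting the single
#' feature with the largest transformed value, since a classifier with no
#' input columns is meaningless.
#'
#' @param position Numeric vector of optimizer coordinates.
#' @param tf_name Transfer function name (default `"S1"`).
#' @param threshold Threshold `T` in (0, 1).
#' @return A list of class `mmg_mask` with `bits` (integer 0/1 vector) and
#'   `R` (number of selected features, always >= 1).
#' @export
binarize <- function(position, tf_name = "S1", threshold = 0.5) {
  if (!(threshold > 0 && threshold < 1))
    stop("'threshold' must lie in (0, 1)")
  v <- transfer(tf_name, position)
  bits <- as.integer(v > threshold)
  if (sum(bits) == 0L) bits[which.max(v)] <- 1L   # repair rule
  structure(list(bits = bits, R = sum(bits)), class = "mmg_mask")
}

#' Wrapper-selection fitness
#'
#' `Fitness = alpha * acc + (1 - alpha) * (1 - R/N)`: a convex combination
#' of the cross-validated accuracy and the fraction of features discarded.
#' The default `alpha = 0.99` puts almost all weight on accuracy with a
#' light parsimony pressure.
#'
#' @param acc Classification accuracy in `[0, 1]`.
#' @param R Number of selected features (`1 <= R <= N`).
#' @param N Total number of features.
#' @param alpha Accuracy weight (default 0.99).
#' @return Fitness in `[0, 1]`.
#' @export
selection_fitness <- function(acc, R, N, alpha = 0.99) {
  if (R > N) stop("'R' cannot exceed 'N'")
  if (R < 1L) stop("'R' must be at least 1")
  if (acc < 0 || acc > 1) stop("'acc' must lie in [0, 1]")
  alpha * acc + (1 - alpha) * (1 - R / N)
}

#' Cross-validation configuration for mask scoring
#'
#' @param k Number of stratified folds (default 10).
#' @param mode `"kfold"` for full k-fold scoring of every candidate mask,
#'   or `"holdout"` for a single stratified train/test split -- a cheaper
#'   surrogate for large wrapper runs.
#' @param holdout_frac Held-out fraction in holdout mode (default 0.25).
#' @param seed Seed fixing the fold assignment.
#' @return A list of class `mmg_cv_config`.
#' @export
cv_config <- function(k = 10L, mode = c("kfold", "holdout"),
                      holdout_frac = 0.25, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(k >= 2L, holdout_frac > 0, holdout_frac < 1)
  structure(list(k = as.integer(k), mode = mode,
                 holdout_frac = holdout_frac, seed = as.integer(seed)),
            class = "mmg_cv_config")
}

#' Stratified fold assignment
#'
#' Assigns each observation to one of `k` folds so that every class is
#' spread as evenly as possible across folds. In `"holdout"` mode fold 1 is
#' the held-out part (about `holdout_frac` of each class) and fold 2 the
#' training part.
#'
#' @param y Label vector.
#' @param cv A [cv_config()].
#' @return Integer vector of fold ids, same length as `y`.
#' @export
make_folds <- function(y, cv = cv_config()) {
  y <- as.character(y)
  folds <- integer(length(y))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cv$seed)
  if (cv$mode == "kfold") {
    tab <- table(y)
    if (any(tab < cv$k))
      stop("class(es) ", paste(names(tab)[tab < cv$k], collapse = ", "),
           " have fewer than k = ", cv$k,
           " members; use a smaller k (at most ", min(tab), ")")
    for (cl in names(tab)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(cv$k), length(idx))
    }
  } else {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      n_test <- max(1L, round(cv$holdout_frac * length(idx)))
      folds[idx] <- c(rep(1L, n_test), rep(2L, length(idx) - n_test))
    }
  }
  folds
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# z-score columns by training statistics; zero-variance columns pass
# through centred only.
zscore_train_test <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(train = sweep(sweep(Xtr, 2L, mu), 2L, sdv, "/"),
       test = sweep(sweep(Xte, 2L, mu), 2L, sdv, "/"),
       center = mu, scale = sdv)
}

#' Score a feature mask by cross-validated SVM accuracy
#'
#' For every fold: features are z-scored with training-fold statistics only
#' (no leakage), an RBF-kernel SVM is trained on the training part
#' restricted to the masked columns, and the held-out part is scored.
#' Held-out predictions are pooled across folds into a row-normalized
#' percent confusion matrix.
#'
#' @param mask An `mmg_mask` from [binarize()], or an integer 0/1 vector.
#' @param features An `mmg_features` object from [build_feature_matrix()].
#' @param cv A [cv_config()].
#' @param folds Optional precomputed fold vector from [make_folds()]; the
#'   wrapper passes a fixed one so all fitness calls are comparable.
#' @param cost,gamma SVM hyperparameters (see [svm_train()]).
#' @return List with `mean_acc`, `fold_acc` (per-fold accuracies),
#'   `confusion` (percent matrix), `class_rates` (its diagonal).
#' @export
evaluate_mask <- function(mask, features, cv = cv_config(), folds = NULL,
                          cost = 10, gamma = NULL) {
  bits <- if (inherits(mask, "mmg_mask")) mask$bits else as.integer(mask)
  if (length(bits) != ncol(features$X))
    stop("mask length does not match the number of features")
  if (sum(bits) < 1L) stop("mask selects no features")
  if (is.null(folds)) folds <- make_folds(features$y, cv)
  X <- features$X[, bits == 1L, drop = FALSE]
  y <- features$y
  fold_ids <- sort(unique(folds[folds > 0L]))
  test_folds <- if (cv$mode == "holdout") 1L else fold_ids
  fold_acc <- numeric(length(test_folds))
  pred_all <- character(length(y)); seen <- logical(length(y))
  for (fi in seq_along(test_folds)) {
    f <- test_folds[fi]
    te <- folds == f
    tr <- !te
    z <- zscore_train_test(X[tr, , drop = FALSE], X[te, , drop = FALSE])
    model <- svm_train(z$train, y[tr], cost = cost, gamma = gamma)
    pred <- predict(model, z$test)
    fold_acc[fi] <- mean(pred == y[te])
    pred_all[te] <- pred; seen[te] <- TRUE
  }
  confusion <- confusion_percent(y[seen], pred_all[seen])
  list(mean_acc = mean(fold_acc), fold_acc = fold_acc,
       confusion = confusion, class_rates = diag(confusion))
}

#' Fold-averaged selection metrics
#'
#' Arithmetic means of the per-fold accuracies and per-fold selected
#' feature counts reported by a wrapper run.
#'
#' @param fold_acc Numeric vector of per-fold accuracies (non-empty).
#' @param fold_R Per-fold selected-feature counts; a scalar is recycled
#'   (the mask, hence R, is constant across folds for a single run).
#' @return List with `mean_acc` and `mean_R`.
#' @export
mean_metrics <- function(fold_acc, fold_R) {
  if (length(fold_acc) == 0L) stop("'fold_acc' is empty")
  fold_R <- rep_len(fold_R, length(fold_acc))
  list(mean_acc = mean(fold_acc), mean_R = mean(fold_R))
}

#' Wrapper feature selection with a swarm optimizer
#'
#' The central fitting function of the package. A continuous swarm
#' optimizer (CSA or GOA) searches the unit box with one coordinate per
#' feature; each candidate position is decoded by a transfer function and
#' threshold `T` into a binary mask ([binarize()]), the mask is scored by
#' cross-validated SVM-RBF accuracy on a fold assignment fixed for the
#' whole run ([evaluate_mask()]), and the optimizer maximizes
#' `alpha * acc + (1 - alpha) * (1 - R/N)` ([selection_fitness()]). The
#' returned model carries the best mask, its full cross-validated report,
#' and a final SVM trained on all rows restricted to the selected features,
#' so [predict.mmg_select()] can classify new segments.
#'
#' The optimizer's dynamics stay continuous; positions are only interpreted
#' as masks at evaluation time. The default search box `[0, 1]` makes the
#' S1-transformed coordinates span `[0.5, 0.731]`, so thresholds between
#' 0.3 and 0.6 walk the solutions from select-all to sparse.
#'
#' @param features An `mmg_features` object from [build_feature_matrix()].
#' @param algorithm `"csa"` or `"goa"`.
#' @param threshold Binarization threshold `T` in (0, 1); default 0.5.
#' @param tf_name Transfer function name; default `"S1"`.
#' @param opt_cfg An [optimizer_config()]; default `N = 20`, `Tmax = 50`
#'   on `[0, 1]^n_features`. Its `dim`, `lb`, `ub` are forced to match the
#'   feature matrix.
#' @param cv A [cv_config()] used both inside the wrapper and for the final
#'   report.
#' @param alpha Fitness accuracy weight (default 0.99).
#' @param cost,gamma SVM hyperparameters.
#' @return An object of class `mmg_select`; see [print.mmg_select()],
#'   [summary.mmg_select()], [coef.mmg_select()], [predict.mmg_select()],
#'   [plot.mmg_select()].
#' @examples
#' \donttest{
#' pd <- generate_planted(n = 120, p = 12, k_informative = 3,
#'                        effect_size = 3, seed = 1)
#' fm <- planted_features(pd)
#' fit <- select_features(fm, "csa", threshold = 0.5,
#'                        opt_cfg = optimizer_config(dim = 12, pop_size = 8,
#'                                                   max_iter = 10, seed = 1),
#'                        cv = cv_config(k = 5))
#' fit
#' }
#' @export
select_features <- function(features, algorithm = c("csa", "goa"),
                            threshold = 0.5, tf_name = "S1",
                            opt_cfg = NULL, cv = cv_config(),
                            alpha = 0.99, cost = 10, gamma = NULL) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(features, "mmg_features"))
  N_feat <- ncol(features$X)
  if (is.null(opt_cfg)) opt_cfg <- optimizer_config(dim = N_feat)
  if (opt_cfg$dim != N_feat) {
    opt_cfg$dim <- N_feat
    opt_cfg$lb <- rep_len(opt_cfg$lb, N_feat)
    opt_cfg$ub <- rep_len(opt_cfg$ub, N_feat)
  }
  folds <- make_folds(features$y, cv)

  # The fold assignment is fixed for the whole run, so a mask's fitness is
  # deterministic: cache it and never score the same mask twice.
  cache <- new.env(hash = TRUE, parent = emptyenv())
  objective <- function(position) {
    mask <- binarize(position, tf_name, threshold)
    key <- paste(mask$bits, collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    res <- evaluate_mask(mask, features, cv, folds, cost, gamma)
    val <- selection_fitness(res$mean_acc, mask$R, N_feat, alpha)
    cache[[key]] <- val
    val
  }
  opt <- optimize_swarm(objective, algorithm, opt_cfg)

  mask <- binarize(opt$best_position, tf_name, threshold)
  report <- evaluate_mask(mask, features, cv, folds, cost, gamma)
  metrics <- mean_metrics(report$fold_acc, mask$R)

  # final model on all rows, selected columns, global z-scoring
  Xsel <- features$X[, mask$bits == 1L, drop = FALSE]
  mu <- colMeans(Xsel)
  sdv <- apply(Xsel, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  Z <- sweep(sweep(Xsel, 2L, mu), 2L, sdv, "/")
  final_model <- svm_train(Z, features$y, cost = cost, gamma = gamma)

  structure(list(mask = mask, feature_names = features$names,
                 selected = features$names[mask$bits == 1L],
                 fitness = opt$best_fitness,
                 fitness_history = opt$fitness_history,
                 fold_acc = report$fold_acc,
                 mean_acc = metrics$mean_acc, mean_R = metrics$mean_R,
                 confusion = report$confusion,
                 class_rates = report$class_rates,
                 threshold = threshold, tf_name = tf_name,
                 algorithm = algorithm, seed = opt_cfg$seed,
                 cv = cv, alpha = alpha, cost = cost, gamma = gamma,
                 center = mu, scale = sdv, model = final_model,
                 evaluations = opt$evaluations),
            class = "mmg_select")
}
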