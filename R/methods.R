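#' @export
print.mmg_mask <- function(x, ...) {
  cat(sprintf("<mmg_mask: %d of %d features selected>\n",
              x$R, length(x$bits)))
  invisible(x)
}

#' Print a fitted feature-selection model
#'
#' @param x An `mmg_select` object from [select_features()].
#' @param ... Unused.
#' @export
print.mmg_select <- function(x, ...) {
  cat(sprintf("Wrapper feature selection (%s, %s transfer, T = %.2f)\n",
              toupper(x$algorithm), x$tf_name, x$threshold))
  cat(sprintf("  selected features : %d of %d\n",
              x$mask$R, length(x$mask$bits)))
  cat(sprintf("  mean CV accuracy  : %.2f%% (%d-fold, %s)\n",
              100 * x$mean_acc, length(x$fold_acc), x$cv$mode))
  cat(sprintf("  fitness           : %.4f (alpha = %.2f)\n",
              x$fitness, x$alpha))
  invisible(x)
}

#' Summarize a fitted feature-selection model
#'
#' Prints the selection summary, the per-class recognition rates (the
#' diagonal of the row-normalized percent confusion matrix) and the
#' confusion matrix itself.
#'
#' @param object An `mmg_select` object.
#' @param ... Unused.
#' @return `object`, invisibly.
#' @export
summary.mmg_select <- function(object, ...) {
  print(object)
  cat("\nPer-class recognition rates (%):\n")
  print(round(object$class_rates, 2))
  cat("\nConfusion matrix (% of true class):\n")
  print(round(object$confusion, 2))
  cat("\nPer-fold accuracies:",
      paste(sprintf("%.3f", object$fold_acc), collapse = " "), "\n")
  invisible(object)
}

#' Selection mask of a fitted model
#'
#' @param object An `mmg_select` object.
#' @param ... Unused.
#' @return Named integer 0/1 vector over all features; 1 = selected.
#' @export
coef.mmg_select <- function(object, ...) {
  stats::setNames(object$mask$bits, object$feature_names)
}

#' Classify new data with a fitted feature-selection model
#'
#' Applies the stored z-scoring (fit-time statistics) and selection mask,
#' then scores the rows with the final SVM trained on all fitting data.
#'
#' @param object An `mmg_select` object.
#' @param newdata An `mmg_features` object or a numeric matrix whose
#'   columns match the features the model was fitted on.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.mmg_select <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "mmg_features")) newdata$X else as.matrix(newdata)
  if (ncol(X) != length(object$mask$bits))
    stop("newdata must have ", length(object$mask$bits), " feature columns")
  Xsel <- X[, object$mask$bits == 1L, drop = FALSE]
  Z <- sweep(sweep(Xsel, 2L, object$center), 2L, object$scale, "/")
  predict(object$model, Z)
}

#' Plot the fitness trace of a feature-selection run
#'
#' Best-so-far wrapper fitness against iteration (0 = after
#' initialization); non-decreasing by construction.
#'
#' @param x An `mmg_select` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mmg_select <- function(x, ...) {
  h <- x$fitness_history
  graphics::plot(seq_along(h) - 1L, h, type = "s",
                 xlab = "iteration", ylab = "best fitness",
                 main = sprintf("%s wrapper selection (T = %.2f)",
                                toupper(x$algorithm), x$threshold), ...)
  invisible(x)
}
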