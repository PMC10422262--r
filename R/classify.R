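#' Train an RBF-kernel support vector machine
#'
#' Thin contract over [e1071::svm()]: a soft-margin C-classification SVM
#' with Gaussian kernel `K(x, x') = exp(-gamma ||x - x'||^2)` and
#' one-vs-one voting for more than two classes. No internal scaling is done
#' (`scale = FALSE`); callers are expected to z-score features from
#' training statistics, as [evaluate_mask()] does per fold.
#'
#' @param X Numeric matrix of training rows (finite values).
#' @param y Labels (coerced to factor); at least two classes.
#' @param cost Penalty parameter C (default 10).
#' @param gamma Kernel width; default `1 / (ncol(X) * mean(apply(X, 2, var)))`,
#'   a data-driven width that reduces to `1/ncol(X)` for z-scored input.
#' @return An object of class `mmg_svm` wrapping the fitted model.
#' @export
svm_train <- function(X, y, cost = 10, gamma = NULL) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2L) stop("training data must contain at least 2 classes")
  if (!all(is.finite(X))) stop("training matrix contains non-finite values")
  if (is.null(gamma)) {
    mv <- mean(apply(X, 2L, stats::var))
    if (!is.finite(mv) || mv <= 0) mv <- 1
    gamma <- 1 / (ncol(X) * mv)
  }
  fit <- e1071::svm(X, y, type = "C-classification", kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE,
                    fitted = FALSE)
  structure(list(fit = fit, levels = levels(y), cost = cost, gamma = gamma,
                 n_features = ncol(X)),
            class = "mmg_svm")
}

#' Predict class labels from a trained SVM
#'
#' @param object An `mmg_svm` model.
#' @param newdata Numeric matrix with the same number of columns the model
#'   was trained on.
#' @param ... Unused.
#' @return Character vector of predicted labels, one per row.
#' @export
predict.mmg_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop("newdata has ", ncol(newdata), " columns; model was trained on ",
         object$n_features)
  as.character(stats::predict(object$fit, newdata))
}

#' Row-normalized percent confusion matrix
#'
#' Entry `(i, j)` is the percentage of class-`i` observations predicted as
#' class `j`; each row sums to 100 and the diagonal holds the per-class
#' recognition rates.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param class_order Row/column order; defaults to the sorted unique true
#'   labels. Every class in `class_order` must occur in `y_true`.
#' @return A numeric `n_classes x n_classes` matrix of percentages.
#' @export
confusion_percent <- function(y_true, y_pred, class_order = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop("'y_true' and 'y_pred' must have equal length")
  if (is.null(class_order)) class_order <- sort(unique(y_true))
  if (!all(y_true %in% class_order) || !all(y_pred %in% class_order))
    stop("labels outside 'class_order'")
  counts <- table(factor(y_true, class_order), factor(y_pred, class_order))
  rs <- rowSums(counts)
  if (any(rs == 0))
    stop("class(es) absent from y_true: ",
         paste(class_order[rs == 0], collapse = ", "))
  m <- 100 * sweep(unclass(counts), 1L, rs, "/")
  dimnames(m) <- list(true = class_order, predicted = class_order)
  m
}
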