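#' Train a soft-margin linear SVM
#'
#' Binary classifier whose decision function is the margin-maximizing
#' hyperplane `y(x) = sum_n w_n * t_n * k(x, x_n) + b` with a linear kernel
#' `k(x, x_n) = <x, x_n>`, where `w_n >= 0` are the dual weights assigned to
#' the training samples, `t_n` their labels, and `b` the bias. The quadratic
#' program is solved by libsvm (via e1071) with no feature scaling; the
#' primal weight vector `primal_w = sum_n w_n * t_n * x_n` is materialized so
#' decisions are a single inner product. The positive class (+1) is
#' progressive MCI + AD.
#'
#' @param X samples x features numeric matrix (finite values).
#' @param y label vector in \{-1, +1\}, both classes present.
#' @param cost_C positive soft-margin cost parameter (default 1).
#' @param tolerance termination tolerance of the underlying QP solver.
#' @return an object of class `svm_model`: `dual_weights` (length-N
#'   non-negative vector, zero for non-support samples), `labels`,
#'   `support_index`, `support_vectors`, `bias`, `primal_w`,
#'   `kernel = "linear"`, `cost_C`, `n_features`.
#' @export
svm_train <- function(X, y, cost_C = 1, tolerance = 1e-6) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop_arg("X must be finite")
  if (nrow(X) != length(y)) stop_arg("X and y disagree on sample count")
  if (!all(y %in% c(-1, 1)) || length(unique(y)) < 2L) {
    stop_arg("y must contain both classes, coded -1/+1")
  }
  assert_scalar_number(cost_C, "cost_C")
  if (cost_C <= 0) stop_arg("cost_C must be positive")
  fit <- e1071::svm(x = X, y = factor(y, levels = c(-1, 1)),
                    type = "C-classification", kernel = "linear",
                    cost = cost_C, scale = FALSE, tolerance = tolerance)
  w <- unname(drop(crossprod(fit$SV, fit$coefs)))
  b <- -fit$rho
  # libsvm's internal sign convention depends on which label it sees first;
  # anchor it to +1 = positive decision by checking against its own predict()
  pred <- as.numeric(as.character(stats::predict(fit, X)))
  ours <- ifelse(drop(X %*% w) + b >= 0, 1, -1)
  if (mean(ours == pred) < 0.5) {
    w <- -w
    b <- -b
  }
  dual <- numeric(nrow(X))
  dual[fit$index] <- abs(fit$coefs)
  structure(
    list(dual_weights = dual,
         labels = y,
         support_index = fit$index,
         support_vectors = X[fit$index, , drop = FALSE],
         bias = b,
         primal_w = w,
         kernel = "linear",
         cost_C = cost_C,
         n_features = ncol(X)),
    class = "svm_model"
  )
}

#' Evaluate the SVM decision function
#'
#' `decision = <primal_w, x> + b`, identical (to numerical tolerance) to the
#' dual expansion `sum_n w_n * t_n * <x, x_n> + b`.
#'
#' @param model an [svm_train()] result.
#' @param x a feature vector or a samples x features matrix.
#' @return numeric decision value(s).
#' @export
svm_decision <- function(model, x) {
  stopifnot(inherits(model, "svm_model"))
  if (!is.matrix(x)) {
    # for a 1-feature model a bare vector is a set of samples, otherwise a
    # single sample
    x <- if (model$n_features == 1L) matrix(x, ncol = 1L) else matrix(x, nrow = 1L)
  }
  if (ncol(x) != model$n_features) {
    stop_arg("x has ", ncol(x), " features, model expects ", model$n_features)
  }
  drop(x %*% model$primal_w) + model$bias
}

#' Classify samples with a trained SVM
#'
#' `sign(decision)`, with a decision of exactly 0 mapped to the positive
#' class (+1).
#'
#' @inheritParams svm_decision
#' @return vector of labels in \{-1, +1\}.
#' @export
svm_classify <- function(model, x) {
  ifelse(svm_decision(model, x) >= 0, 1, -1)
}

#' Confusion-matrix performance metrics
#'
#' The positive class (+1) is progressive MCI + AD, so sensitivity is the
#' detection rate of subjects on the path to dementia and specificity the
#' correct-rejection rate of stable subjects. An empty stratum leaves the
#' corresponding ratio `NA` (undefined), never silently 0.
#'
#' @param y_true,y_pred equal-length label vectors in \{-1, +1\}.
#' @return object of class `metrics`: counts `tp`, `tn`, `fp`, `fn` and
#'   ratios `accuracy`, `sensitivity`, `specificity`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop_arg("y_true and y_pred must have equal length")
  }
  if (!all(c(y_true, y_pred) %in% c(-1, 1))) {
    stop_arg("labels must be coded -1/+1")
  }
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == -1 & y_pred == -1)
  fp <- sum(y_true == -1 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == -1)
  structure(
    list(tp = tp, tn = tn, fp = fp, fn = fn,
         accuracy = (tp + tn) / (tp + tn + fp + fn),
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_),
    class = "metrics"
  )
}

#' @export
print.metrics <- function(x, ...) {
  cat(sprintf("<metrics> acc %.3f | sens %s | spec %s (tp %d tn %d fp %d fn %d)\n",
              x$accuracy, format(x$sensitivity, digits = 3),
              format(x$specificity, digits = 3), x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}
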