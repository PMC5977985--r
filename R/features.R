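#' Fisher-discriminant-ratio feature ranking
#'
#' Ranks feature columns by their univariate class-discriminatory power,
#' `(mu_A - mu_B)^2 / (var_A + var_B)`, where A is the negative class
#' (label -1, controls + stable MCI) and B the positive class (+1,
#' progressive MCI + AD), using sample variances (denominator n - 1).
#' A zero denominator with a non-zero numerator (perfectly separated,
#' zero-variance feature) yields `+Inf` and ranks first; 0/0 yields 0.
#' Ties are broken by ascending original column index.
#'
#' @param X samples x features numeric matrix.
#' @param y label vector in \{-1, +1\}, one per row of `X`.
#' @return an object of class `ranking_result`: `order` (feature indices,
#'   best first), `fdr_values` (aligned with `order`, non-increasing), and
#'   per-class `stats` (`mu_A`, `mu_B`, `var_A`, `var_B` per feature).
#' @export
fdr_rank <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop_arg("X and y disagree on sample count")
  if (!all(y %in% c(-1, 1))) stop_arg("y must contain only -1 and +1")
  a <- y == -1
  b <- y == 1
  if (sum(a) < 2L || sum(b) < 2L) {
    stop_arg("fdr_rank needs at least 2 samples in each class")
  }
  mu_a <- colMeans(X[a, , drop = FALSE])
  mu_b <- colMeans(X[b, , drop = FALSE])
  var_a <- apply(X[a, , drop = FALSE], 2L, stats::var)
  var_b <- apply(X[b, , drop = FALSE], 2L, stats::var)
  num <- (mu_a - mu_b)^2
  den <- var_a + var_b
  fdr <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  ord <- order(-fdr)  # stable: ties keep ascending original index
  structure(
    list(order = ord,
         fdr_values = fdr[ord],
         stats = list(mu_A = mu_a, mu_B = mu_b, var_A = var_a, var_B = var_b)),
    class = "ranking_result"
  )
}

#' Principal component analysis of training data
#'
#' Fits the orthogonal transformation onto the training covariance
#' eigenvectors, sorted by explained variance (descending). At most
#' `n_samples - 1` components carry non-zero variance, so a cohort of 200
#' subjects yields at most 199 coefficients per sample. The sign of each
#' loading column is fixed so its largest-magnitude entry is positive
#' (eigenvector sign is otherwise arbitrary).
#'
#' @param X_train samples x features numeric matrix (>= 2 rows).
#' @param n_components requested number of components; capped at
#'   `min(n_samples - 1, n_features)`. `NULL` keeps the cap.
#' @return an object of class `pca_model`: `mean`, `loadings` (features x
#'   components, orthonormal columns), `explained_variance` (non-increasing),
#'   `n_components`.
#' @export
pca_fit <- function(X_train, n_components = NULL) {
  X_train <- as.matrix(X_train)
  n <- nrow(X_train)
  if (n < 2L) stop_arg("pca_fit needs at least 2 training samples")
  k_max <- min(n - 1L, ncol(X_train))
  k <- if (is.null(n_components)) k_max else min(as.integer(n_components), k_max)
  if (k < 1L) stop_arg("n_components must be >= 1")
  mu <- colMeans(X_train)
  Xc <- sweep(X_train, 2L, mu)
  if (ncol(Xc) > n) {
    # wide data: eigendecompose the n x n Gram matrix instead of the
    # feature covariance; loadings are recovered as t(Xc) u / sigma
    eg <- eigen(tcrossprod(Xc), symmetric = TRUE)
    d2 <- pmax(eg$values[seq_len(k)], 0)
    keep <- d2 > max(d2) * 1e-12
    k <- max(1L, sum(keep))
    d2 <- d2[seq_len(k)]
    loadings <- crossprod(Xc, eg$vectors[, seq_len(k), drop = FALSE])
    loadings <- sweep(loadings, 2L, sqrt(d2), "/")
    ev <- d2 / (n - 1L)
  } else {
    sv <- svd(Xc, nu = 0L, nv = k)
    loadings <- sv$v
    ev <- (sv$d[seq_len(k)]^2) / (n - 1L)
  }
  # deterministic sign: largest-|entry| of each component positive
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  structure(
    list(mean = mu, loadings = loadings, explained_variance = ev,
         n_components = k),
    class = "pca_model"
  )
}

#' Project samples onto a fitted PCA subspace
#'
#' @param X samples x features matrix with the model's feature dimension.
#' @param model a [pca_fit()] result.
#' @return samples x n_components coefficient matrix.
#' @export
pca_transform <- function(X, model) {
  stopifnot(inherits(model, "pca_model"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$mean)) {
    stop_arg("X has ", ncol(X), " features, model expects ",
             length(model$mean))
  }
  sweep(X, 2L, model$mean) %*% model$loadings
}

#' Partial least squares feature extraction
#'
#' Projection directions that maximize covariance between the (centered)
#' features and the (centered) class labels, computed by iterative deflation
#' (NIPALS, single response): the first direction is proportional to
#' `t(Xc) %*% yc`, normalized to unit length; each subsequent direction is
#' computed after deflating `X` by the fitted component's loading.
#'
#' @param X_train samples x features matrix.
#' @param y label vector in \{-1, +1\}.
#' @param n_components number of components, at most
#'   `min(n_samples - 1, n_features)`.
#' @return object of class `pls_model`: `x_mean`, `weights` (unit-norm
#'   projection directions, features x components), `loadings` (deflation
#'   loadings used when transforming new samples), `n_components`.
#' @export
pls_fit <- function(X_train, y, n_components) {
  X_train <- as.matrix(X_train)
  n <- nrow(X_train)
  if (n != length(y)) stop_arg("X_train and y disagree on sample count")
  if (!all(y %in% c(-1, 1)) || length(unique(y)) < 2L) {
    stop_arg("y must contain both classes, coded -1/+1")
  }
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > min(n - 1L, ncol(X_train))) {
    stop_arg("n_components out of range [1, min(n_samples - 1, n_features)]")
  }
  mu <- colMeans(X_train)
  Xc <- sweep(X_train, 2L, mu)
  yc <- y - mean(y)
  p <- ncol(Xc)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  for (k in seq_len(n_components)) {
    w <- drop(crossprod(Xc, yc))
    nrm <- sqrt(sum(w^2))
    if (nrm < .Machine$double.eps^0.5) {
      # no residual covariance with the labels: any unit direction is
      # equally (un)informative; pick the first coordinate for determinism
      w <- c(1, rep(0, p - 1L))
    } else {
      w <- w / nrm
    }
    t_k <- drop(Xc %*% w)
    tt <- sum(t_k^2)
    p_k <- if (tt > 0) drop(crossprod(Xc, t_k)) / tt else w
    Xc <- Xc - tcrossprod(t_k, p_k)
    W[, k] <- w
    P[, k] <- p_k
  }
  structure(
    list(x_mean = mu, weights = W, loadings = P, n_components = n_components),
    class = "pls_model"
  )
}

#' Project samples onto fitted PLS components
#'
#' Applies the same center-project-deflate sequence used during fitting, so
#' training data reproduce the fitted (mutually uncorrelated) scores.
#'
#' @param X samples x features matrix.
#' @param model a [pls_fit()] result.
#' @param n_components optionally use only the first components.
#' @return samples x n_components score matrix.
#' @export
pls_transform <- function(X, model, n_components = NULL) {
  stopifnot(inherits(model, "pls_model"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$x_mean)) {
    stop_arg("X has ", ncol(X), " features, model expects ",
             length(model$x_mean))
  }
  k <- n_components %||% model$n_components
  if (k < 1L || k > model$n_components) stop_arg("n_components out of range")
  Xc <- sweep(X, 2L, model$x_mean)
  scores <- matrix(0, nrow(X), k)
  for (j in seq_len(k)) {
    t_j <- drop(Xc %*% model$weights[, j])
    scores[, j] <- t_j
    Xc <- Xc - tcrossprod(t_j, model$loadings[, j])
  }
  scores
}

#' Z-score normalization fitted on training data
#'
#' @param X_train samples x columns matrix of neuropsychological scores.
#' @return object of class `zscore_stats` with per-column training `mean`
#'   and sample standard deviation `sd`.
#' @export
zscore_fit <- function(X_train) {
  X_train <- as.matrix(X_train)
  if (nrow(X_train) < 2L) stop_arg("zscore_fit needs >= 2 training samples")
  structure(
    list(mean = colMeans(X_train),
         sd = apply(X_train, 2L, stats::sd),
         names = colnames(X_train)),
    class = "zscore_stats"
  )
}

#' Apply fitted z-score normalization
#'
#' Columns with zero training standard deviation are mapped to all zeros,
#' with a warning (a constant score carries no class information).
#'
#' @param X samples x columns matrix, same width as the fitted stats.
#' @param stats a [zscore_fit()] result.
#' @return normalized matrix of the same shape.
#' @export
zscore_apply <- function(X, stats) {
  stopifnot(inherits(stats, "zscore_stats"))
  X <- as.matrix(X)
  if (ncol(X) != length(stats$mean)) {
    stop_arg("X has ", ncol(X), " columns, stats expect ", length(stats$mean))
  }
  sd <- stats$sd
  zero <- sd == 0
  if (any(zero)) {
    warning("constant score column(s) mapped to zero: ",
            paste(which(zero), collapse = ", "), call. = FALSE)
    sd[zero] <- 1
  }
  out <- sweep(sweep(X, 2L, stats$mean), 2L, sd, "/")
  out[, zero] <- 0
  out
}

#' Assemble the classifier feature matrix from both streams
#'
#' Horizontally concatenates the top `k_mri` ranked MRI coefficients (PCA or
#' PLS components) and the top `k_np` ranked neuropsychological scores, with
#' a provenance label per column (`"mri:<component#>"` or `"np:<name>"`) so
#' every model weight can be traced back to its source.
#'
#' @param mri_coeffs samples x components matrix (may be `NULL` if
#'   `k_mri = 0`).
#' @param score_matrix samples x scores matrix (may be `NULL` if `k_np = 0`).
#' @param mri_ranking,score_ranking [fdr_rank()] results for the two streams
#'   (ignored for a stream with k = 0).
#' @param k_mri,k_np how many top-ranked columns to keep from each stream;
#'   `k_mri + k_np >= 1`.
#' @return samples x (k_mri + k_np) matrix; `colnames` are the provenance
#'   labels and attribute `"provenance"` is a data.frame with columns
#'   `label`, `stream` (`"mri"`/`"np"`), `source_index`.
#' @export
assemble_features <- function(mri_coeffs, score_matrix,
                              mri_ranking = NULL, score_ranking = NULL,
                              k_mri, k_np) {
  k_mri <- as.integer(k_mri)
  k_np <- as.integer(k_np)
  if (k_mri < 0L || k_np < 0L) stop_arg("k_mri and k_np must be >= 0")
  if (k_mri + k_np < 1L) stop_arg("k_mri + k_np must be >= 1")
  parts <- list()
  prov <- list()
  if (k_mri > 0L) {
    if (is.null(mri_coeffs) || is.null(mri_ranking)) {
      stop_arg("k_mri > 0 requires mri_coeffs and mri_ranking")
    }
    if (k_mri > ncol(mri_coeffs)) stop_arg("k_mri exceeds available components")
    idx <- mri_ranking$order[seq_len(k_mri)]
    parts$mri <- as.matrix(mri_coeffs)[, idx, drop = FALSE]
    prov$mri <- data.frame(label = paste0("mri:", idx),
                           stream = "mri", source_index = idx,
                           stringsAsFactors = FALSE)
  }
  if (k_np > 0L) {
    if (is.null(score_matrix) || is.null(score_ranking)) {
      stop_arg("k_np > 0 requires score_matrix and score_ranking")
    }
    if (k_np > ncol(score_matrix)) stop_arg("k_np exceeds available scores")
    idx <- score_ranking$order[seq_len(k_np)]
    nm <- colnames(score_matrix) %||% paste0("score", seq_len(ncol(score_matrix)))
    parts$np <- as.matrix(score_matrix)[, idx, drop = FALSE]
    prov$np <- data.frame(label = paste0("np:", nm[idx]),
                          stream = "np", source_index = idx,
                          stringsAsFactors = FALSE)
  }
  out <- do.call(cbind, parts)
  provenance <- do.call(rbind, prov)
  rownames(provenance) <- NULL
  colnames(out) <- provenance$label
  attr(out, "provenance") <- provenance
  out
}
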