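CHANNEL_ORDER <- c("whole_brain", "GM", "WM")
FWHM_GRID <- c(0, 2, 4, 6, 8, 10, 12)

#' Wrapper search grid
#'
#' The candidate configurations searched by the inner loop: tissue channel,
#' smoothing FWHM (0 = no smoothing; the declared grid is 0, 2, 4, ..., 12
#' mm), number of retained MRI components `k_mri`, and number of retained
#' neuropsychological scores `k_np`. Every row must satisfy
#' `k_mri + k_np >= 1`.
#'
#' @param channels subset of `"whole_brain"`, `"GM"`, `"WM"`.
#' @param fwhm_mm subset of `c(0, 2, 4, 6, 8, 10, 12)`.
#' @param k_mri,k_np candidate feature counts (k_mri is the number of PCA
#'   coefficients, or of PLS components when the extractor is PLS; values
#'   beyond what the training data support are capped at fit time).
#' @return data.frame with columns `channel`, `fwhm_mm`, `k_mri`, `k_np`.
#' @export
default_grid <- function(channels = CHANNEL_ORDER,
                         fwhm_mm = FWHM_GRID,
                         k_mri = c(1, 2, 5, 10, 20, 50),
                         k_np = c(0, 1, 2, 5, 10, 20, 64)) {
  if (!all(channels %in% CHANNEL_ORDER)) stop_arg("unknown channel")
  if (!all(fwhm_mm %in% FWHM_GRID)) {
    stop_arg("fwhm_mm must lie in the declared grid {",
             paste(FWHM_GRID, collapse = ", "), "}")
  }
  g <- expand.grid(channel = channels, fwhm_mm = fwhm_mm, k_mri = k_mri,
                   k_np = k_np, stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[g$k_mri + g$k_np >= 1, , drop = FALSE]
  rownames(g) <- NULL
  g
}

check_grid <- function(grid) {
  need <- c("channel", "fwhm_mm", "k_mri", "k_np")
  if (!is.data.frame(grid) || !all(need %in% names(grid)) || nrow(grid) == 0L) {
    stop_arg("grid must be a non-empty data.frame with columns ",
             paste(need, collapse = ", "))
  }
  if (!all(grid$channel %in% CHANNEL_ORDER)) stop_arg("unknown channel in grid")
  if (!all(grid$fwhm_mm %in% FWHM_GRID)) {
    stop_arg("grid fwhm_mm must lie in {", paste(FWHM_GRID, collapse = ", "), "}")
  }
  if (any(grid$k_mri < 0) || any(grid$k_np < 0) ||
      any(grid$k_mri + grid$k_np < 1)) {
    stop_arg("grid rows must have k_mri, k_np >= 0 and k_mri + k_np >= 1")
  }
  grid
}

#' Stratified nested cross-validation partition
#'
#' Splits `n` samples into `k_outer` outer folds; within each outer fold's
#' training portion, `k_inner` inner folds are formed the same way. Folds
#' are stratified: class proportions are preserved within +/- 1 sample, so a
#' balanced 200-subject cohort under 5x5 nested CV gives, in every round,
#' 128 training, 32 validation and 40 outer-test subjects.
#'
#' @param n sample count.
#' @param k_outer,k_inner fold counts (each >= 2).
#' @param y label vector (length `n`) used for stratification.
#' @param seed integer seed; the partition is deterministic given the seed.
#' @return list of `k_outer` splits, each with `outer_fold_id`, `test_ids`,
#'   `train_ids` (the complementary 4/5), and `inner`, a list of `k_inner`
#'   lists with `train_ids` and `validation_ids` (subsets of the outer
#'   `train_ids`).
#' @export
nested_partition <- function(n, k_outer, k_inner, y, seed) {
  if (length(y) != n) stop_arg("y must have length n")
  if (k_outer < 2L || n < k_outer) stop_arg("need n >= k_outer >= 2")
  if (k_inner < 2L) stop_arg("k_inner must be >= 2")
  classes <- unique(y)
  if (any(table(y) < k_outer)) {
    stop_arg("every class needs at least k_outer samples to stratify")
  }
  with_rng(seed, {
    fold_of <- integer(n)
    for (cl in classes) {
      ids <- which(y == cl)
      fold_of[ids] <- rep_len(seq_len(k_outer), length(ids))[sample.int(length(ids))]
    }
    lapply(seq_len(k_outer), function(f) {
      test_ids <- which(fold_of == f)
      train_ids <- which(fold_of != f)
      y_tr <- y[train_ids]
      if (any(table(y_tr) < k_inner)) {
        stop_arg("every class needs at least k_inner samples in the outer ",
                 "training portion")
      }
      inner_fold <- integer(length(train_ids))
      for (cl in classes) {
        pos <- which(y_tr == cl)
        inner_fold[pos] <- rep_len(seq_len(k_inner), length(pos))[sample.int(length(pos))]
      }
      inner <- lapply(seq_len(k_inner), function(g) {
        list(train_ids = train_ids[inner_fold != g],
             validation_ids = train_ids[inner_fold == g])
      })
      list(outer_fold_id = f, test_ids = test_ids, train_ids = train_ids,
           inner = inner)
    })
  })
}

# Caching provider of smoothed, flattened MRI feature matrices for one
# timepoint: provider(channel, fwhm_mm) -> subjects x voxels matrix.
# Smoothing is per-subject and label-free, so matrices can be shared across
# folds and across permutation iterations.
make_feature_provider <- function(bundle, timepoint) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  if (!timepoint %in% names(bundle$volumes)) {
    stop_arg("bundle has no timepoint '", timepoint, "'")
  }
  shape <- bundle$grid$shape
  vox <- bundle$grid$voxel_size_mm
  cache <- new.env(parent = emptyenv())
  function(channel, fwhm_mm) {
    key <- sprintf("%s|%g", channel, fwhm_mm)
    if (!is.null(cache[[key]])) return(cache[[key]])
    M <- bundle$volumes[[timepoint]][[channel]]
    if (is.null(M)) stop_arg("bundle has no channel '", channel,
                             "' at timepoint '", timepoint, "'")
    if (fwhm_mm > 0) {
      A <- array(t(M), dim = c(shape, nrow(M)))
      sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
      for (axis in 1:3) {
        K <- gaussian_axis_matrix(shape[axis], sigma_mm / vox[axis])
        A <- apply_along_axis(A, K, axis)
      }
      M <- t(matrix(A, nrow = prod(shape)))
      rownames(M) <- rownames(bundle$volumes[[timepoint]][[channel]])
    }
    cache[[key]] <- M
    M
  }
}

identity_ranking <- function(k) {
  structure(list(order = seq_len(k), fdr_values = rep(NA_real_, k),
                 stats = NULL),
            class = "ranking_result")
}

# Fit the MRI feature-extraction stream on training rows only and return a
# projector plus the ranking used to pick components.
fit_mri_stream <- function(X_train, y_train, extractor, max_k) {
  if (extractor == "pca_fdr") {
    pca <- pca_fit(X_train)
    coeffs_train <- pca_transform(X_train, pca)
    ranking <- fdr_rank(coeffs_train, y_train)
    list(project = function(X) pca_transform(X, pca),
         ranking = ranking, model = pca, n_components = pca$n_components)
  } else if (extractor == "pls") {
    k <- min(max_k, nrow(X_train) - 1L, ncol(X_train))
    pls <- pls_fit(X_train, y_train, n_components = k)
    list(project = function(X) pls_transform(X, pls),
         ranking = identity_ranking(k), model = pls, n_components = k)
  } else {
    stop_arg("unknown extractor '", extractor, "'")
  }
}

# Fit both feature streams on the training rows of one partition and build
# assembled feature matrices for arbitrary grid rows. The fitted projections
# are applied to the full cohort matrix once per stream (projection is
# row-wise, so this leaks nothing); grid rows then only index rows/columns.
fit_partition <- function(ctx, train_ids, extractor, grid) {
  y_train <- ctx$y[train_ids]
  need_mri <- any(grid$k_mri > 0)
  need_np <- any(grid$k_np > 0)
  mri <- list()
  if (need_mri) {
    combos <- unique(grid[grid$k_mri > 0, c("channel", "fwhm_mm")])
    for (i in seq_len(nrow(combos))) {
      ch <- combos$channel[i]
      fw <- combos$fwhm_mm[i]
      X <- ctx$provider(ch, fw)
      max_k <- max(grid$k_mri[grid$channel == ch & grid$fwhm_mm == fw])
      stream <- fit_mri_stream(X[train_ids, , drop = FALSE], y_train,
                               extractor, max_k)
      stream$coeffs_all <- stream$project(X)
      mri[[sprintf("%s|%g", ch, fw)]] <- stream
    }
  }
  np <- NULL
  if (need_np) {
    S_train <- ctx$scores[train_ids, , drop = FALSE]
    zs <- zscore_fit(S_train)
    Z_train <- suppressWarnings(zscore_apply(S_train, zs))
    np <- list(zs = zs, ranking = fdr_rank(Z_train, y_train),
               z_all = suppressWarnings(zscore_apply(ctx$scores, zs)))
  }
  list(train_ids = train_ids, y_train = y_train, mri = mri, np = np,
       extractor = extractor)
}

# Assembled feature matrix for arbitrary cohort rows under one grid row.
partition_features <- function(part, ctx, ids, gp) {
  k_mri <- gp$k_mri
  k_np <- gp$k_np
  mri_coeffs <- NULL
  mri_ranking <- NULL
  if (k_mri > 0) {
    stream <- part$mri[[sprintf("%s|%g", gp$channel, gp$fwhm_mm)]]
    mri_coeffs <- stream$coeffs_all[ids, , drop = FALSE]
    mri_ranking <- stream$ranking
    k_mri <- min(k_mri, ncol(mri_coeffs))
  }
  scores <- NULL
  score_ranking <- NULL
  if (k_np > 0) {
    scores <- part$np$z_all[ids, , drop = FALSE]
    score_ranking <- part$np$ranking
    k_np <- min(k_np, ncol(scores))
  }
  assemble_features(mri_coeffs, scores, mri_ranking, score_ranking,
                    k_mri = k_mri, k_np = k_np)
}

#' Inner-loop wrapper selection
#'
#' For each grid point, fits the feature streams and the SVM on every inner
#' training partition, evaluates accuracy on the matching validation
#' partition, and averages over the inner folds; returns the grid point that
#' maximizes mean validation accuracy. Ties are broken toward smaller
#' `k_mri`, then smaller `k_np`, then smaller FWHM, then channel order
#' whole-brain < GM < WM.
#'
#' @param ctx context list with `provider` (see `make_feature_provider`),
#'   `scores` (subjects x scores matrix) and `y` (labels); built internally
#'   by [run_nested_cv()].
#' @param inner_folds list of inner folds (`train_ids`, `validation_ids`).
#' @param grid search grid as in [default_grid()].
#' @param extractor `"pca_fdr"` or `"pls"`.
#' @param cost_C SVM cost.
#' @return list with `chosen` (one grid row plus `extractor`),
#'   `inner_accuracy`, and `accuracies` (per-grid-row mean validation
#'   accuracy, in tie-break order).
#' @export
inner_select <- function(ctx, inner_folds, grid, extractor = "pca_fdr",
                         cost_C = 1) {
  grid <- check_grid(grid)
  ord <- order(grid$k_mri, grid$k_np, grid$fwhm_mm,
               match(grid$channel, CHANNEL_ORDER))
  grid <- grid[ord, , drop = FALSE]
  rownames(grid) <- NULL
  acc <- matrix(NA_real_, length(inner_folds), nrow(grid))
  for (f in seq_along(inner_folds)) {
    fold <- inner_folds[[f]]
    part <- fit_partition(ctx, fold$train_ids, extractor, grid)
    for (g in seq_len(nrow(grid))) {
      gp <- grid[g, ]
      F_tr <- partition_features(part, ctx, fold$train_ids, gp)
      F_va <- partition_features(part, ctx, fold$validation_ids, gp)
      fit <- svm_train(F_tr, ctx$y[fold$train_ids], cost_C = cost_C)
      acc[f, g] <- mean(svm_classify(fit, F_va) == ctx$y[fold$validation_ids])
    }
  }
  mean_acc <- colMeans(acc)
  best <- which.max(mean_acc)  # first max = tie-break order
  chosen <- grid[best, , drop = FALSE]
  chosen$extractor <- extractor
  rownames(chosen) <- NULL
  list(chosen = chosen, inner_accuracy = mean_acc[best],
       accuracies = cbind(grid, mean_accuracy = mean_acc))
}

#' Run the full nested cross-validation pipeline
#'
#' For each outer fold: wrapper selection on the inner folds of the 4/5
#' training portion; refit of the chosen configuration on the full 4/5
#' portion (training + validation); evaluation on the untouched 1/5 outer
#' test set. Every fit — PCA/PLS, z-scoring, FDR ranking, SVM — uses only
#' data from its own fold's training side. Fold metrics are summarized as
#' mean +/- sd (n - 1) over the outer folds.
#'
#' @param bundle a `cohort_bundle`.
#' @param timepoint which timepoint to analyse (e.g. `"m24"`).
#' @param modality `"mri_plus_np"` (both streams) or `"mri_only"` (forces
#'   `k_np = 0`).
#' @param extractor `"pca_fdr"` or `"pls"`.
#' @param grid search grid; defaults to [default_grid()].
#' @param seed integer seed for the partition.
#' @param k_outer,k_inner fold counts (default fivefold nested CV).
#' @param cost_C SVM soft-margin cost (default 1; the wrapper grid does not
#'   search over it).
#' @param keep_fold_artifacts keep per-fold fitted models and training
#'   features, needed by [importance_map()]; set `FALSE` to save memory.
#' @param .provider internal: reuse a smoothed-feature cache across runs on
#'   bundles sharing the same volumes (used by [permutation_test()]).
#' @return object of class `performance_summary`: `summary` data.frame
#'   (metric, mean, sd), `folds` (per-fold chosen configuration, inner
#'   validation accuracy, test metrics, selected feature labels, artifacts),
#'   plus the run settings.
#' @export
run_nested_cv <- function(bundle, timepoint,
                          modality = c("mri_plus_np", "mri_only"),
                          extractor = c("pca_fdr", "pls"),
                          grid = default_grid(),
                          seed = 1L, k_outer = 5L, k_inner = 5L,
                          cost_C = 1, keep_fold_artifacts = TRUE,
                          .provider = NULL) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  modality <- match.arg(modality)
  extractor <- match.arg(extractor)
  grid <- check_grid(grid)
  if (!timepoint %in% names(bundle$volumes)) {
    stop_arg("bundle has no timepoint '", timepoint, "'")
  }
  if (modality == "mri_only") {
    grid$k_np <- 0
    grid <- unique(grid)
    grid <- grid[grid$k_mri >= 1, , drop = FALSE]
    if (nrow(grid) == 0L) stop_arg("mri_only needs grid rows with k_mri >= 1")
  }
  y <- bundle$subjects$binary_label
  splits <- nested_partition(nrow(bundle$subjects), k_outer, k_inner, y, seed)
  ctx <- list(provider = .provider %||% make_feature_provider(bundle, timepoint),
              scores = bundle$scores[[timepoint]],
              y = y)
  folds <- lapply(splits, function(sp) {
    sel <- inner_select(ctx, sp$inner, grid, extractor, cost_C)
    part <- fit_partition(ctx, sp$train_ids, extractor, sel$chosen)
    F_tr <- partition_features(part, ctx, sp$train_ids, sel$chosen)
    F_te <- partition_features(part, ctx, sp$test_ids, sel$chosen)
    fit <- svm_train(F_tr, y[sp$train_ids], cost_C = cost_C)
    metrics <- compute_metrics(y[sp$test_ids], svm_classify(fit, F_te))
    artifacts <- NULL
    if (keep_fold_artifacts) {
      key <- sprintf("%s|%g", sel$chosen$channel, sel$chosen$fwhm_mm)
      artifacts <- list(
        svm = fit,
        train_features = F_tr,
        provenance = attr(F_tr, "provenance"),
        mri_model = if (sel$chosen$k_mri > 0) part$mri[[key]]$model else NULL
      )
    }
    list(outer_fold_id = sp$outer_fold_id,
         chosen = sel$chosen,
         inner_validation_accuracy = sel$inner_accuracy,
         metrics = metrics,
         selected_feature_labels = colnames(F_tr),
         artifacts = artifacts)
  })
  metric_names <- c("accuracy", "sensitivity", "specificity")
  per_fold <- sapply(metric_names, function(m) {
    sapply(folds, function(f) f$metrics[[m]])
  })
  summary <- data.frame(
    metric = metric_names,
    mean = colMeans(per_fold),
    sd = apply(per_fold, 2L, stats::sd),
    row.names = NULL
  )
  structure(
    list(summary = summary, folds = folds, timepoint = timepoint,
         modality = modality, extractor = extractor, seed = seed,
         k_outer = k_outer, k_inner = k_inner, cost_C = cost_C),
    class = "performance_summary"
  )
}

#' Per-fold values of one metric
#'
#' @param x a `performance_summary`.
#' @param metric `"accuracy"`, `"sensitivity"` or `"specificity"`.
#' @return numeric vector, one value per outer fold, in fold order.
#' @export
fold_metric <- function(x, metric = "accuracy") {
  stopifnot(inherits(x, "performance_summary"))
  sapply(x$folds, function(f) f$metrics[[metric]])
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf("<performance_summary> %s / %s / %s (%dx%d nested CV)\n",
              x$timepoint, x$modality, x$extractor, x$k_outer, x$k_inner))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-11s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}
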