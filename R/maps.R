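#' Back-project SVM weights into voxel space
#'
#' For a model trained on PCA coefficients, the coefficient-space weight
#' vector (the dual expansion `sum_n w_n t_n x_n`, restricted to the MRI
#' columns identified by the feature provenance) is mapped back to voxels
#' through the PCA loadings; neuropsychological columns are excluded.
#'
#' @param model an [svm_train()] result fitted on assembled features.
#' @param pca the [pca_fit()] model that produced the MRI coefficients.
#' @param provenance the `"provenance"` attribute of the assembled feature
#'   matrix the model was trained on.
#' @return numeric vector over voxels (flattened order).
#' @export
primal_voxel_weights <- function(model, pca, provenance) {
  stopifnot(inherits(model, "svm_model"), inherits(pca, "pca_model"))
  if (is.null(provenance)) stop_arg("feature provenance is required")
  mri <- provenance$stream == "mri"
  if (!any(mri)) stop_arg("model has no MRI features to back-project")
  comps <- provenance$source_index[mri]
  drop(pca$loadings[, comps, drop = FALSE] %*% model$primal_w[mri])
}

#' Activation pattern of a linear backward model
#'
#' Converts a discriminative weight vector into its forward-model
#' counterpart `A = Cov(X_train) %*% w`, computed in the feature space where
#' the model was trained. Backward-model weights can assign large values to
#' noise-cancelling features; the activation pattern is the quantity that is
#' interpretable as class-related signal.
#'
#' @param X_train samples x features training matrix (>= 2 rows).
#' @param w weight vector of matching length.
#' @return numeric activation vector of the same length as `w`.
#' @export
activation_pattern <- function(X_train, w) {
  X_train <- as.matrix(X_train)
  if (nrow(X_train) < 2L) stop_arg("need >= 2 training samples")
  if (ncol(X_train) != length(w)) {
    stop_arg("w has length ", length(w), ", X_train has ", ncol(X_train),
             " features")
  }
  drop(stats::cov(X_train) %*% w)
}

# Voxel importance map of one outer fold: activation-pattern correction in
# the trained feature space, then back-projection of the MRI part through
# the fold's PCA loadings.
fold_voxel_map <- function(fold, use_activation = TRUE) {
  art <- fold$artifacts
  if (is.null(art)) stop_arg("fold artifacts were not kept; rerun with ",
                             "keep_fold_artifacts = TRUE")
  if (is.null(art$mri_model) || !inherits(art$mri_model, "pca_model")) {
    stop_arg("voxel maps require a fold fitted with the PCA+FDR extractor ",
             "and k_mri >= 1")
  }
  prov <- art$provenance
  w <- if (use_activation) {
    activation_pattern(art$train_features, art$svm$primal_w)
  } else {
    art$svm$primal_w
  }
  mri <- prov$stream == "mri"
  comps <- prov$source_index[mri]
  drop(art$mri_model$loadings[, comps, drop = FALSE] %*% w[mri])
}

#' Aggregate per-fold voxel maps into a normalized importance map
#'
#' Averages the absolute per-fold values voxelwise (absolute values so
#' opposing fold signs do not cancel discriminative voxels), then min-max
#' normalizes the mean map to \[0, 1\]. The threshold (default 0.35, i.e.
#' 35% of the normalized range) is stored and applied in the `thresholded`
#' variant, where sub-threshold voxels are zeroed. A constant mean map
#' yields an all-zero output with a warning.
#'
#' @param per_fold_maps list of equal-length voxel vectors.
#' @param grid_shape length-3 grid dimensions for reshaping.
#' @param threshold display threshold in \[0, 1\].
#' @param signed average signed values instead of magnitudes.
#' @return object of class `importance_map`: `values` (3D array in \[0, 1\]),
#'   `thresholded` (same with sub-threshold voxels zeroed), `threshold`,
#'   `n_folds`.
#' @export
aggregate_maps <- function(per_fold_maps, grid_shape, threshold = 0.35,
                           signed = FALSE) {
  if (!is.list(per_fold_maps) || length(per_fold_maps) == 0L) {
    stop_arg("per_fold_maps must be a non-empty list")
  }
  if (threshold < 0 || threshold > 1) stop_arg("threshold must be in [0, 1]")
  lens <- lengths(per_fold_maps)
  if (length(unique(lens)) != 1L || lens[1L] != prod(grid_shape)) {
    stop_arg("maps must all have length prod(grid_shape)")
  }
  M <- do.call(rbind, per_fold_maps)
  m <- if (signed) colMeans(M) else colMeans(abs(M))
  rng <- range(m)
  if (diff(rng) == 0) {
    warning("constant mean map; returning all zeros", call. = FALSE)
    norm <- rep(0, length(m))
  } else {
    norm <- (m - rng[1L]) / diff(rng)
  }
  values <- array(norm, dim = grid_shape)
  thresholded <- values
  thresholded[thresholded < threshold] <- 0
  structure(
    list(values = values, thresholded = thresholded, threshold = threshold,
         n_folds = length(per_fold_maps)),
    class = "importance_map"
  )
}

#' Fold-averaged voxel importance map of a nested-CV run
#'
#' Builds the per-fold voxel maps (SVM weights, activation-pattern
#' corrected, back-projected through each fold's PCA loadings), averages
#' them across the outer folds, and min-max normalizes to \[0, 1\]. Only
#' defined for runs with the PCA+FDR extractor and `k_mri >= 1` in every
#' fold's chosen configuration.
#'
#' @param x a [run_nested_cv()] result with kept fold artifacts.
#' @param grid_shape voxel grid dimensions (e.g. `bundle$grid$shape`).
#' @param threshold display threshold (default 0.35).
#' @param use_activation apply the activation-pattern correction (default
#'   `TRUE`); `FALSE` back-projects the raw weights.
#' @param signed average signed per-fold maps instead of magnitudes.
#' @return an `importance_map`, with `provenance` (timepoint, extractor,
#'   folds averaged) attached.
#' @export
importance_map <- function(x, grid_shape, threshold = 0.35,
                           use_activation = TRUE, signed = FALSE) {
  stopifnot(inherits(x, "performance_summary"))
  maps <- lapply(x$folds, fold_voxel_map, use_activation = use_activation)
  out <- aggregate_maps(maps, grid_shape, threshold = threshold,
                        signed = signed)
  out$provenance <- list(timepoint = x$timepoint, extractor = x$extractor,
                         n_folds = length(x$folds))
  out
}

#' Export an importance map as NIfTI
#'
#' Writes both the raw-normalized and the thresholded variant.
#'
#' @param map an [importance_map()] / [aggregate_maps()] result.
#' @param path_raw,path_thresholded output NIfTI paths.
#' @param voxel_size_mm voxel size for the header.
#' @return invisibly, the two paths.
#' @export
write_importance_map <- function(map, path_raw, path_thresholded = NULL,
                                 voxel_size_mm = c(2, 2, 2)) {
  stopifnot(inherits(map, "importance_map"))
  write_volume(volume_grid(map$values, voxel_size_mm = voxel_size_mm),
               path_raw)
  if (!is.null(path_thresholded)) {
    write_volume(volume_grid(map$thresholded, voxel_size_mm = voxel_size_mm),
                 path_thresholded)
  }
  invisible(c(path_raw, path_thresholded))
}

#' Neuropsychological predictor frequency table
#'
#' Frequency with which each score was selected across the nested-CV rounds:
#' `frequency = (#rounds whose selected set contains the score) / #rounds`.
#' Rows are sorted by frequency descending (ties by name); rows with
#' frequency strictly above the cutoff (default 0.05, i.e. 5%) are flagged
#' as best predictors.
#'
#' @param selected_per_round list (one element per round) of character
#'   vectors of selected feature labels; only labels prefixed `"np:"` (or
#'   bare score names if no `"np:"` labels are present) are counted.
#' @param cutoff flagging cutoff in \[0, 1\].
#' @param universe optional character vector of all candidate score names,
#'   so never-selected scores appear with frequency 0.
#' @return object of class `predictor_frequency_table`, a data.frame with
#'   columns `name`, `frequency`, `flagged`.
#' @export
predictor_frequency <- function(selected_per_round, cutoff = 0.05,
                                universe = NULL) {
  if (!is.list(selected_per_round) || length(selected_per_round) == 0L) {
    stop_arg("need at least one round")
  }
  n_rounds <- length(selected_per_round)
  np_names <- lapply(selected_per_round, function(labels) {
    labels <- as.character(labels)
    if (any(grepl("^(np|mri):", labels))) {
      sub("^np:", "", labels[grepl("^np:", labels)])
    } else {
      labels
    }
  })
  all_names <- sort(unique(c(unlist(np_names), universe)))
  freq <- vapply(all_names, function(nm) {
    mean(vapply(np_names, function(s) nm %in% s, logical(1)))
  }, numeric(1))
  ord <- order(-freq, all_names)
  out <- data.frame(name = all_names[ord], frequency = unname(freq[ord]),
                    flagged = unname(freq[ord]) > cutoff,
                    stringsAsFactors = FALSE)
  attr(out, "cutoff") <- cutoff
  attr(out, "n_rounds") <- n_rounds
  class(out) <- c("predictor_frequency_table", "data.frame")
  out
}

#' Predictor frequency table of a nested-CV run
#'
#' @param x a [run_nested_cv()] result.
#' @param cutoff flagging cutoff (default 0.05).
#' @param universe optional vector of all candidate score names (e.g.
#'   `colnames(bundle$scores[[timepoint]])`).
#' @return a [predictor_frequency()] table.
#' @export
np_predictor_frequency <- function(x, cutoff = 0.05, universe = NULL) {
  stopifnot(inherits(x, "performance_summary"))
  predictor_frequency(lapply(x$folds, `[[`, "selected_feature_labels"),
                      cutoff = cutoff, universe = universe)
}
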