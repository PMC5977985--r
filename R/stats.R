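#' Permutation p-value from a null sample
#'
#' The p-value is the fraction of null values greater than or equal to the
#' observed value. With `smoothed = TRUE` the add-one estimator
#' `(r + 1) / (n + 1)` is used instead (never exactly zero); the plain
#' fraction is the default. Resolution is `1 / n_iter`: a p-value below that
#' cannot be resolved and is reported as 0 (plain) or `1 / (n + 1)`
#' (smoothed).
#'
#' @param null_values numeric vector of metric values under permuted labels.
#' @param observed observed metric value.
#' @param smoothed use the add-one estimator.
#' @return p-value in \[0, 1\].
#' @export
permutation_pvalue <- function(null_values, observed, smoothed = FALSE) {
  if (length(null_values) < 1L) stop_arg("need at least one null value")
  r <- sum(null_values >= observed)
  if (smoothed) (r + 1) / (length(null_values) + 1) else r / length(null_values)
}

#' Permutation significance test of the full pipeline
#'
#' Reruns the complete nested cross-validation — including inner wrapper
#' selection — under random permutations of the diagnostic labels, and
#' reports, for each performance metric, the fraction of permuted-label runs
#' whose metric is greater than or equal to the observed one. Rerunning the
#' whole selection inside every iteration keeps selection-induced optimism
#' in the null distribution. The reference study design uses 1000
#' iterations; `n_iter` is configurable for desk-scale work.
#'
#' @inheritParams run_nested_cv
#' @param n_iter number of label permutations (>= 1).
#' @param smoothed report add-one smoothed p-values (default `FALSE`,
#'   matching the plain-fraction definition).
#' @return object of class `permutation_result`: `observed` (the unpermuted
#'   `performance_summary`), `null_distributions` (n_iter x 3 matrix of fold-mean
#'   accuracy/sensitivity/specificity), `p_values`, `n_iter`, `seed`.
#' @export
permutation_test <- function(bundle, timepoint,
                             modality = c("mri_plus_np", "mri_only"),
                             extractor = c("pca_fdr", "pls"),
                             grid = default_grid(),
                             n_iter = 1000L, seed = 1L,
                             k_outer = 5L, k_inner = 5L, cost_C = 1,
                             smoothed = FALSE) {
  modality <- match.arg(modality)
  extractor <- match.arg(extractor)
  n_iter <- as.integer(n_iter)
  if (n_iter < 1L) stop_arg("n_iter must be >= 1")
  provider <- make_feature_provider(bundle, timepoint)
  run1 <- function(b) {
    run_nested_cv(b, timepoint, modality, extractor, grid, seed = seed,
                  k_outer = k_outer, k_inner = k_inner, cost_C = cost_C,
                  keep_fold_artifacts = FALSE, .provider = provider)
  }
  observed <- run1(bundle)
  metric_names <- c("accuracy", "sensitivity", "specificity")
  null <- matrix(NA_real_, n_iter, 3L, dimnames = list(NULL, metric_names))
  for (i in seq_len(n_iter)) {
    res <- run1(permute_labels(bundle, seed = seed + i))
    null[i, ] <- res$summary$mean[match(metric_names, res$summary$metric)]
  }
  obs <- observed$summary$mean[match(metric_names, observed$summary$metric)]
  p <- vapply(seq_along(metric_names), function(j) {
    permutation_pvalue(null[, j], obs[j], smoothed = smoothed)
  }, numeric(1))
  names(p) <- metric_names
  structure(
    list(observed = observed, null_distributions = null, p_values = p,
         n_iter = n_iter, seed = seed, smoothed = smoothed),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %d iterations (resolution %.4g)\n",
              x$n_iter, 1 / x$n_iter))
  for (m in names(x$p_values)) {
    cat(sprintf("  %-11s p = %.4g\n", m, x$p_values[[m]]))
  }
  invisible(x)
}

#' Paired comparison of fold-matched performance
#'
#' Two-sided paired-sample t-test on the per-fold differences of a metric
#' between two pipeline configurations evaluated on the same folds (e.g.
#' PCA+FDR vs. PLS, or MRI-only vs. multimodal). All-zero differences give
#' statistic 0 and p = 1.
#'
#' @param metric_per_fold_A,metric_per_fold_B equal-length (>= 2) numeric
#'   vectors in matched fold order.
#' @return object of class `comparison_result`: `statistic`, `p_value`,
#'   `test = "paired_t"`, `dof`.
#' @export
paired_comparison <- function(metric_per_fold_A, metric_per_fold_B) {
  a <- as.numeric(metric_per_fold_A)
  b <- as.numeric(metric_per_fold_B)
  if (length(a) != length(b)) stop_arg("fold vectors must have equal length")
  if (length(a) < 2L) stop_arg("need at least 2 folds")
  d <- a - b
  if (all(d == 0) || stats::sd(d) == 0 && mean(d) == 0) {
    res <- list(statistic = 0, p_value = 1)
  } else if (stats::sd(d) == 0) {
    res <- list(statistic = sign(mean(d)) * Inf, p_value = 0)
  } else {
    tt <- stats::t.test(a, b, paired = TRUE)
    res <- list(statistic = unname(tt$statistic), p_value = tt$p.value)
  }
  structure(
    list(statistic = res$statistic, p_value = res$p_value,
         test = "paired_t", dof = length(a) - 1L),
    class = "comparison_result"
  )
}

#' One-way ANOVA of a metric across time points
#'
#' Fixed-effects one-way ANOVA of per-fold metric values grouped by time
#' point, with optional unadjusted all-pairs follow-up t-tests. Groups that
#' are all identical constants give F = 0 and p = 1.
#'
#' @param metric_per_fold named list of numeric vectors (>= 2 groups, each
#'   with >= 2 values), one per time point.
#' @param follow_up also compute unadjusted pairwise two-sample t-tests.
#' @return object of class `comparison_result`: `statistic` (F), `p_value`,
#'   `test = "one_way_anova"`, `dof` (c(between, within)); with
#'   `follow_up = TRUE`, a `pairwise` data.frame of unadjusted p-values.
#' @export
anova_timepoints <- function(metric_per_fold, follow_up = FALSE) {
  if (!is.list(metric_per_fold) || length(metric_per_fold) < 2L) {
    stop_arg("need at least 2 groups")
  }
  sizes <- lengths(metric_per_fold)
  if (any(sizes < 2L)) stop_arg("every group needs at least 2 values")
  values <- unlist(metric_per_fold, use.names = FALSE)
  labels <- names(metric_per_fold) %||% paste0("g", seq_along(metric_per_fold))
  g <- factor(rep(labels, sizes), levels = labels)
  df1 <- nlevels(g) - 1L
  df2 <- length(values) - nlevels(g)
  if (stats::var(values) == 0) {
    f_stat <- 0
    p <- 1
  } else {
    ow <- stats::oneway.test(values ~ g, var.equal = TRUE)
    f_stat <- unname(ow$statistic)
    p <- ow$p.value
    if (!is.finite(f_stat)) {  # zero within-group variance, nonzero between
      f_stat <- Inf
      p <- 0
    }
  }
  pairwise <- NULL
  if (follow_up) {
    combos <- utils::combn(labels, 2L)
    pairwise <- data.frame(
      group_a = combos[1L, ], group_b = combos[2L, ],
      p_value = apply(combos, 2L, function(pair) {
        x <- metric_per_fold[[pair[1L]]]
        y <- metric_per_fold[[pair[2L]]]
        if (stats::sd(c(x, y)) == 0) return(1)
        stats::t.test(x, y, var.equal = TRUE)$p.value
      }),
      stringsAsFactors = FALSE
    )
    attr(pairwise, "adjustment") <- "none (unadjusted all-pairs t-tests)"
  }
  structure(
    list(statistic = f_stat, p_value = p, test = "one_way_anova",
         dof = c(between = df1, within = df2), pairwise = pairwise),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: statistic %.4g, p = %.4g (dof %s)\n",
              x$test, x$statistic, x$p_value, paste(x$dof, collapse = ", ")))
  invisible(x)
}
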