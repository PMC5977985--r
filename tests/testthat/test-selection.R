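test_that("nested partitions have the design sizes and partition the cohort", {
  y200 <- rep(c(-1, 1), each = 100)
  splits <- nested_partition(200, 5, 5, y200, seed = 1)
  for (sp in splits) {
    expect_length(sp$test_ids, 40)
    expect_length(sp$train_ids, 160)
    for (f in sp$inner) {
      expect_length(f$train_ids, 128)
      expect_length(f$validation_ids, 32)
      expect_length(intersect(f$train_ids, f$validation_ids), 0)
      expect_length(intersect(f$validation_ids, sp$test_ids), 0)
      expect_length(intersect(f$train_ids, sp$test_ids), 0)
    }
    # stratification: class proportions preserved within +/- 1 sample
    expect_equal(sum(y200[sp$test_ids] == 1), 20)
  }
  all_test <- sort(unlist(lapply(splits, `[[`, "test_ids")))
  expect_equal(all_test, 1:200)

  # n = 50 balanced, 5x5: |test| = 10, |train| = 32, |validation| = 8
  y50 <- rep(c(-1, 1), each = 25)
  s50 <- nested_partition(50, 5, 5, y50, seed = 2)
  expect_length(s50[[1]]$test_ids, 10)
  expect_length(s50[[1]]$inner[[1]]$train_ids, 32)
  expect_length(s50[[1]]$inner[[1]]$validation_ids, 8)

  expect_identical(nested_partition(50, 5, 5, y50, seed = 2), s50)
  expect_error(nested_partition(8, 5, 2, rep(c(-1, 1), 4), 1), "stratify")
})

test_that("wrapper selection returns the singleton grid and honors tie-breaks", {
  b <- separable_cohort(seed = 1, n_per_class = 10)
  y <- b$subjects$binary_label
  splits <- nested_partition(nrow(b$subjects), 5, 3, y, seed = 1)
  ctx <- list(provider = mcipredict:::make_feature_provider(b, "t0"),
              scores = b$scores$t0, y = y)

  single <- data.frame(channel = "GM", fwhm_mm = 4, k_mri = 2, k_np = 0)
  sel <- inner_select(ctx, splits[[1]]$inner, single)
  expect_equal(sel$chosen$channel, "GM")
  expect_equal(sel$chosen$k_mri, 2)

  # saturated accuracy on a strongly separable cohort: both points tie at
  # 1.0 and the smaller k_mri wins
  ties <- data.frame(channel = "GM", fwhm_mm = 4, k_mri = c(2, 5), k_np = 0)
  sel <- inner_select(ctx, splits[[1]]$inner, ties)
  expect_equal(max(sel$accuracies$mean_accuracy), 1)
  expect_equal(sel$chosen$k_mri, 2)
  expect_equal(sel$inner_accuracy, 1)

  expect_error(inner_select(ctx, splits[[1]]$inner,
                            data.frame(channel = character(0),
                                       fwhm_mm = numeric(0),
                                       k_mri = integer(0),
                                       k_np = integer(0))),
               "non-empty")
})

test_that("wrapper selection prefers planted features over pure noise", {
  # strong score effect, no volume effect: the scores-only grid point must
  # beat the WM-volume (pure noise) point
  b <- generate_cohort(cohort_config(
    n_per_class = 20, grid_shape = c(6, 6, 6), timepoints = "t0",
    effect_delta_by_timepoint = c(t0 = 0), base_smooth_fwhm_mm = 0,
    n_scores = 8, n_informative_scores = 3, score_effect_d = 2.5, seed = 3))
  y <- b$subjects$binary_label
  splits <- nested_partition(nrow(b$subjects), 5, 3, y, seed = 1)
  ctx <- list(provider = mcipredict:::make_feature_provider(b, "t0"),
              scores = b$scores$t0, y = y)
  grid <- data.frame(channel = "WM", fwhm_mm = 0,
                     k_mri = c(3, 0), k_np = c(0, 3))
  sel <- inner_select(ctx, splits[[1]]$inner, grid)
  expect_equal(sel$chosen$k_np, 3)
  expect_equal(sel$chosen$k_mri, 0)
  acc <- sel$accuracies
  expect_gt(acc$mean_accuracy[acc$k_np == 3], acc$mean_accuracy[acc$k_np == 0])
})

test_that("nested CV is deterministic and summarizes fold metrics exactly", {
  b <- separable_cohort(seed = 2, n_per_class = 10)
  g <- small_grid()
  r1 <- run_nested_cv(b, "t0", "mri_plus_np", "pca_fdr", g, seed = 3,
                      k_inner = 3, keep_fold_artifacts = FALSE)
  r2 <- run_nested_cv(b, "t0", "mri_plus_np", "pca_fdr", g, seed = 3,
                      k_inner = 3, keep_fold_artifacts = FALSE)
  expect_identical(r1$summary, r2$summary)
  expect_identical(lapply(r1$folds, `[[`, "chosen"),
                   lapply(r2$folds, `[[`, "chosen"))
  # reported means are the arithmetic fold means, sd over folds (n - 1)
  expect_equal(r1$summary$mean[r1$summary$metric == "accuracy"],
               mean(fold_metric(r1, "accuracy")))
  expect_equal(r1$summary$sd[r1$summary$metric == "accuracy"],
               sd(fold_metric(r1, "accuracy")))
  expect_error(run_nested_cv(b, "m12", grid = g), "timepoint")
})

test_that("mri_only forces k_np to zero in every chosen configuration", {
  b <- separable_cohort(seed = 4, n_per_class = 10)
  r <- run_nested_cv(b, "t0", "mri_only", "pca_fdr",
                     small_grid(), seed = 1, k_inner = 3,
                     keep_fold_artifacts = FALSE)
  expect_true(all(sapply(r$folds, function(f) f$chosen$k_np) == 0))
  expect_true(all(grepl("^mri:", unlist(lapply(r$folds,
                                               `[[`, "selected_feature_labels")))))
})

test_that("outer-fold selection never looks at its own test samples", {
  b <- separable_cohort(seed = 5, n_per_class = 10)
  g <- data.frame(channel = "GM", fwhm_mm = c(0, 4), k_mri = 2, k_np = 2)
  r <- run_nested_cv(b, "t0", "mri_plus_np", "pca_fdr", g, seed = 7,
                     k_inner = 3, keep_fold_artifacts = FALSE)
  # perturb the first fold's outer-test samples wildly
  splits <- nested_partition(nrow(b$subjects), 5, 3,
                             b$subjects$binary_label, seed = 7)
  ids <- splits[[1]]$test_ids
  b2 <- b
  for (ch in names(b2$volumes$t0)) {
    b2$volumes$t0[[ch]][ids, ] <- b2$volumes$t0[[ch]][ids, ] + 50
  }
  b2$scores$t0[ids, ] <- b2$scores$t0[ids, ] - 50
  r2 <- run_nested_cv(b2, "t0", "mri_plus_np", "pca_fdr", g, seed = 7,
                      k_inner = 3, keep_fold_artifacts = FALSE)
  expect_identical(r$folds[[1]]$chosen, r2$folds[[1]]$chosen)
  expect_equal(r$folds[[1]]$inner_validation_accuracy,
               r2$folds[[1]]$inner_validation_accuracy)
})

test_that("the PLS extractor drives the same engine to high accuracy", {
  b <- separable_cohort(seed = 6, n_per_class = 10)
  r <- run_nested_cv(b, "t0", "mri_plus_np", "pls",
                     data.frame(channel = "GM", fwhm_mm = 4,
                                k_mri = c(2, 4), k_np = 2),
                     seed = 1, k_inner = 3, keep_fold_artifacts = FALSE)
  expect_gte(r$summary$mean[r$summary$metric == "accuracy"], 0.9)
  expect_true(all(sapply(r$folds, function(f) f$chosen$extractor) == "pls"))
})

test_that("accuracy responds monotonically to the planted effect size", {
  accs <- sapply(c(0, 0.3, 5), function(delta) {
    b <- generate_cohort(cohort_config(
      n_per_class = 15, grid_shape = c(8, 8, 8), timepoints = "t0",
      effect_delta_by_timepoint = c(t0 = delta), base_smooth_fwhm_mm = 4,
      n_scores = 4, n_informative_scores = 0, seed = 21))
    r <- run_nested_cv(b, "t0", "mri_only", "pca_fdr",
                       data.frame(channel = "GM", fwhm_mm = 4,
                                  k_mri = c(2, 5), k_np = 0),
                       seed = 1, k_inner = 3, keep_fold_artifacts = FALSE)
    c(r$summary$mean[r$summary$metric == "accuracy"],
      sd(fold_metric(r)) / sqrt(r$k_outer))
  })
  # non-decreasing across {null, small, large}, allowing 1 fold-SE slack
  expect_gte(accs[1, 2], accs[1, 1] - max(accs[2, 1], 0.05))
  expect_gte(accs[1, 3], accs[1, 2] - max(accs[2, 2], 0.05))
  expect_gte(accs[1, 3], 0.95)
})
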