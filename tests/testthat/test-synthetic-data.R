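test_that("cohort generation is bit-identical for identical configurations", {
  cfg <- cohort_config(n_per_class = 4, grid_shape = c(6, 6, 6),
                       n_scores = 5, seed = 17)
  b1 <- generate_cohort(cfg)
  b2 <- generate_cohort(cfg)
  expect_identical(b1, b2)
  b3 <- generate_cohort(cohort_config(n_per_class = 4, grid_shape = c(6, 6, 6),
                                      n_scores = 5, seed = 18))
  expect_false(identical(b1$volumes, b3$volumes))
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(grid_shape = c(2, 6, 6)), ">= 3 voxels")
  expect_error(cohort_config(effect_mask = c(0, 5)), "inside grid_shape")
  expect_error(cohort_config(effect_mask = prod(c(20, 24, 20)) + 1),
               "inside grid_shape")
  expect_error(
    cohort_config(effect_delta_by_timepoint = c(m24 = 1, m18 = 0.5,
                                                m12 = 0.5, t0 = 0.5)),
    "non-decreasing")
  expect_error(cohort_config(n_scores = 4, n_informative_scores = 5),
               "n_informative_scores")
})

test_that("subjects carry the group-to-binary-label mapping and balanced counts", {
  b <- generate_cohort(cohort_config(n_per_class = 6, grid_shape = c(5, 5, 5),
                                     n_scores = 4, seed = 1))
  s <- b$subjects
  expect_equal(sum(s$binary_label == -1), 6)
  expect_equal(sum(s$binary_label == 1), 6)
  expect_true(all(s$group[s$binary_label == -1] %in% c("CN", "sMCI")))
  expect_true(all(s$group[s$binary_label == 1] %in% c("pMCI", "AD")))
  # one volume per (timepoint x channel), one score row per timepoint
  expect_equal(names(b$volumes), c("m24", "m18", "m12", "t0"))
  for (tp in names(b$volumes)) {
    expect_equal(names(b$volumes[[tp]]), c("whole_brain", "GM", "WM"))
    expect_equal(dim(b$volumes[[tp]]$GM), c(12L, 125L))
    expect_equal(dim(b$scores[[tp]]), c(12L, 4L))
  }
})

test_that("a large planted effect separates masked means with zero training error", {
  cfg <- cohort_config(n_per_class = 10, grid_shape = c(8, 8, 8),
                       timepoints = "t0",
                       effect_delta_by_timepoint = c(t0 = 5),
                       noise_sd = 1, base_smooth_fwhm_mm = 0,
                       n_scores = 3, seed = 5)
  b <- generate_cohort(cfg)
  masked_mean <- rowMeans(b$volumes$t0$GM[, b$truth$effect_mask, drop = FALSE])
  y <- b$subjects$binary_label
  thr <- (max(masked_mean[y == 1]) + min(masked_mean[y == -1])) / 2
  expect_true(all(masked_mean[y == 1] < thr))
  expect_true(all(masked_mean[y == -1] > thr))
  # the effect is planted in GM only
  wm_mean <- rowMeans(b$volumes$t0$WM[, b$truth$effect_mask, drop = FALSE])
  expect_gt(t.test(wm_mean[y == 1], wm_mean[y == -1])$p.value, 0.001)
})

test_that("standardized masked group difference is non-decreasing across timepoints", {
  cfg <- cohort_config(n_per_class = 40, grid_shape = c(8, 8, 8),
                       effect_delta_by_timepoint = c(m24 = 0.2, m18 = 0.5,
                                                     m12 = 1, t0 = 2),
                       base_smooth_fwhm_mm = 0, n_scores = 3, seed = 8)
  b <- generate_cohort(cfg)
  y <- b$subjects$binary_label
  d <- sapply(names(b$volumes), function(tp) {
    mm <- rowMeans(b$volumes[[tp]]$GM[, b$truth$effect_mask, drop = FALSE])
    (mean(mm[y == -1]) - mean(mm[y == 1])) / sd(mm)
  })
  expect_true(all(diff(d) > 0))
})

test_that("null cohorts give uniform two-sample p-values on the masked mean", {
  p <- sapply(1:40, function(s) {
    cfg <- cohort_config(n_per_class = 10, grid_shape = c(6, 6, 6),
                         timepoints = "t0",
                         effect_delta_by_timepoint = c(t0 = 0),
                         base_smooth_fwhm_mm = 0, n_scores = 2,
                         n_informative_scores = 0, seed = 100 + s)
    b <- generate_cohort(cfg)
    mm <- rowMeans(b$volumes$t0$GM[, b$truth$effect_mask, drop = FALSE])
    t.test(mm[b$subjects$binary_label == 1],
           mm[b$subjects$binary_label == -1])$p.value
  })
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
})

test_that("cohorts roundtrip through NIfTI + CSV serialization", {
  b <- generate_cohort(cohort_config(n_per_class = 2, grid_shape = c(5, 6, 5),
                                     timepoints = c("m12", "t0"),
                                     n_scores = 3, seed = 2))
  dir <- local_tempdir()
  manifest <- write_cohort(b, file.path(dir, "cohort"))
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  # manifest lists n_subjects x n_timepoints x n_channels volumes
  expect_length(m$volumes, 4 * 2 * 3)
  back <- read_cohort(manifest)
  for (tp in names(b$volumes)) {
    for (ch in names(b$volumes[[tp]])) {
      expect_equal(back$volumes[[tp]][[ch]], b$volumes[[tp]][[ch]],
                   tolerance = 1e-6)
    }
    expect_equal(back$scores[[tp]], b$scores[[tp]], tolerance = 1e-9)
  }
  expect_equal(back$subjects, b$subjects)
  expect_equal(back$truth$effect_mask, b$truth$effect_mask)
})

test_that("writing to an unusable location fails without a manifest", {
  b <- generate_cohort(cohort_config(n_per_class = 2, grid_shape = c(5, 5, 5),
                                     timepoints = "t0", n_scores = 2, seed = 3))
  dir <- local_tempdir()
  blocker <- file.path(dir, "blocker")
  writeLines("not a directory", blocker)
  target <- file.path(blocker, "cohort")  # parent is a plain file
  expect_error(suppressWarnings(write_cohort(b, target)), "writable")
  expect_false(file.exists(file.path(target, "manifest.json")))
})

test_that("label permutation shuffles labels but not data", {
  b <- generate_cohort(cohort_config(n_per_class = 10, grid_shape = c(5, 5, 5),
                                     timepoints = "t0", n_scores = 3, seed = 4))
  bp <- permute_labels(b, seed = 1)
  expect_identical(bp$volumes, b$volumes)
  expect_identical(bp$scores, b$scores)
  expect_equal(sort(bp$subjects$binary_label), sort(b$subjects$binary_label))
  expect_identical(permute_labels(b, seed = 1), bp)
})
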