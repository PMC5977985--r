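COHORT_CHANNELS <- c("whole_brain", "GM", "WM")

#' Spherical effect mask
#'
#' Convenience builder for a ball of voxels, the generator's stand-in for a
#' spatially localized atrophy region (e.g. medial-temporal).
#'
#' @param grid_shape length-3 integer grid dimensions.
#' @param center voxel coordinates of the sphere center (1-based); default is
#'   slightly off-center.
#' @param radius radius in voxels.
#' @return integer vector of linear voxel indices (column-major).
#' @export
sphere_mask <- function(grid_shape, center = NULL, radius = 3) {
  grid_shape <- as.integer(grid_shape)
  if (is.null(center)) center <- round(grid_shape / 2) + c(2, -3, 1)
  center <- pmin(pmax(center, 1), grid_shape)
  idx <- arrayInd(seq_len(prod(grid_shape)), grid_shape)
  d2 <- rowSums(sweep(idx, 2L, center)^2)
  which(d2 <= radius^2)
}

#' Configuration of a synthetic longitudinal cohort
#'
#' Describes a two-class longitudinal cohort emulating the study design the
#' pipeline targets: two balanced diagnostic groups (controls + stable MCI
#' vs. progressive MCI + AD), four time points running up to the moment of
#' stable diagnosis, three registered volume channels per subject and time
#' point (whole-brain, GM, WM), and a table of neuropsychological scores.
#' The group difference is planted as a mean intensity decrement (an atrophy
#' surrogate) inside a known voxel mask of the GM channel, with a magnitude
#' that grows toward the diagnosis time point; a small subset of score
#' columns is shifted between classes by a known standardized effect.
#'
#' @param n_per_class subjects per binary class (default 100, i.e. a
#'   200-subject cohort).
#' @param grid_shape 3 positive integers, voxels per axis (default
#'   `c(20, 24, 20)`); every axis must have at least 3 voxels.
#' @param voxel_size_mm voxel size in mm (default 2 mm isotropic).
#' @param timepoints ordered labels, earliest first (default
#'   `c("m24", "m18", "m12", "t0")`: 24, 18, 12 months before stable
#'   diagnosis, and the stable-diagnosis point).
#' @param effect_mask linear voxel indices carrying the group difference;
#'   default is a [sphere_mask()] of radius 3.
#' @param effect_delta_by_timepoint named non-negative numeric, mean
#'   intensity decrement in the positive class per time point, non-decreasing
#'   along `timepoints`; default ramps from 0.12 to 0.24 in units of
#'   `noise_sd`, giving moderate voxelwise standardized effects relative to
#'   the intrinsically smoothed noise.
#' @param noise_sd standard deviation of the baseline voxel noise.
#' @param base_smooth_fwhm_mm intrinsic spatial smoothness applied to the
#'   noise before the effect is planted (default 4 mm).
#' @param n_scores number of neuropsychological score columns (default 64).
#' @param n_informative_scores number of score columns that differ between
#'   classes (default 8, capped at `n_scores`).
#' @param score_effect_d standardized mean class difference of the
#'   informative score columns (default 0.8).
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_class = 100L,
                          grid_shape = c(20L, 24L, 20L),
                          voxel_size_mm = c(2, 2, 2),
                          timepoints = c("m24", "m18", "m12", "t0"),
                          effect_mask = NULL,
                          effect_delta_by_timepoint = NULL,
                          noise_sd = 1,
                          base_smooth_fwhm_mm = 4,
                          n_scores = 64L,
                          n_informative_scores = min(8L, n_scores),
                          score_effect_d = 0.8,
                          seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 3L)) {
    stop_arg("grid_shape must give >= 3 voxels per axis")
  }
  if (n_per_class < 2L) stop_arg("n_per_class must be >= 2")
  if (length(timepoints) < 1L || anyDuplicated(timepoints)) {
    stop_arg("timepoints must be distinct labels")
  }
  if (is.null(effect_mask)) effect_mask <- sphere_mask(grid_shape)
  effect_mask <- as.integer(effect_mask)
  if (any(effect_mask < 1L) || any(effect_mask > prod(grid_shape))) {
    stop_arg("effect_mask indices must lie inside grid_shape")
  }
  if (is.null(effect_delta_by_timepoint)) {
    effect_delta_by_timepoint <- stats::setNames(
      noise_sd * seq(0.12, 0.24, length.out = length(timepoints)), timepoints)
  }
  if (!all(timepoints %in% names(effect_delta_by_timepoint))) {
    stop_arg("effect_delta_by_timepoint must name every timepoint")
  }
  deltas <- effect_delta_by_timepoint[timepoints]
  if (any(deltas < 0)) stop_arg("effect deltas must be non-negative")
  if (any(diff(deltas) < 0)) {
    stop_arg("effect deltas must be non-decreasing along the timepoint order")
  }
  if (noise_sd <= 0) stop_arg("noise_sd must be positive")
  if (base_smooth_fwhm_mm < 0) stop_arg("base_smooth_fwhm_mm must be >= 0")
  n_scores <- as.integer(n_scores)
  n_informative_scores <- as.integer(n_informative_scores)
  if (n_scores < 1L) stop_arg("n_scores must be >= 1")
  if (n_informative_scores < 0L || n_informative_scores > n_scores) {
    stop_arg("n_informative_scores must lie in [0, n_scores]")
  }
  structure(
    list(n_per_class = as.integer(n_per_class),
         grid_shape = grid_shape,
         voxel_size_mm = as.numeric(voxel_size_mm),
         timepoints = timepoints,
         effect_mask = effect_mask,
         effect_delta_by_timepoint = deltas,
         noise_sd = noise_sd,
         base_smooth_fwhm_mm = base_smooth_fwhm_mm,
         n_scores = n_scores,
         n_informative_scores = n_informative_scores,
         score_effect_d = score_effect_d,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Generate a synthetic longitudinal cohort
#'
#' Volumes are baseline Gaussian noise (`sd = noise_sd`), smoothed to the
#' configured intrinsic smoothness, after which `effect_delta` is subtracted
#' inside `effect_mask` for positive-class subjects — in the GM channel only,
#' so the wrapper's tissue-map choice has a recoverable ground truth. The
#' informative score columns of the positive class are shifted by
#' `score_effect_d` standard deviations; remaining columns are pure noise.
#' The result is bit-identical across calls with the same configuration.
#'
#' @param config a [cohort_config()].
#' @return an object of class `cohort_bundle`: `subjects` (data.frame with
#'   `subject_id`, `group` in CN/sMCI/pMCI/AD, `binary_label` -1/+1),
#'   `volumes[[timepoint]][[channel]]` (subjects x voxels matrices, voxels in
#'   the fixed column-major order of [flatten_masked()]),
#'   `scores[[timepoint]]` (subjects x n_scores matrices), `grid`
#'   (shape/voxel size), `config`, and `truth` (`effect_mask`,
#'   `informative_scores`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- 2L * config$n_per_class
  V <- prod(config$grid_shape)
  group <- c(
    rep(c("CN", "sMCI"), c(ceiling(config$n_per_class / 2),
                           floor(config$n_per_class / 2))),
    rep(c("pMCI", "AD"), c(ceiling(config$n_per_class / 2),
                           floor(config$n_per_class / 2)))
  )
  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = group,
    binary_label = rep(c(-1, 1), each = config$n_per_class),
    stringsAsFactors = FALSE
  )
  pos <- subjects$binary_label == 1
  with_rng(config$seed, {
    informative <- if (config$n_informative_scores > 0L) {
      sort(sample.int(config$n_scores, config$n_informative_scores))
    } else {
      integer(0)
    }
    volumes <- list()
    scores <- list()
    for (tp in config$timepoints) {
      delta <- config$effect_delta_by_timepoint[[tp]]
      volumes[[tp]] <- list()
      for (ch in COHORT_CHANNELS) {
        M <- matrix(stats::rnorm(n * V, sd = config$noise_sd), nrow = n)
        if (config$base_smooth_fwhm_mm > 0) {
          for (i in seq_len(n)) {
            M[i, ] <- as.numeric(smooth_array(
              array(M[i, ], dim = config$grid_shape),
              config$base_smooth_fwhm_mm, config$voxel_size_mm))
          }
        }
        if (ch == "GM" && delta > 0) {
          M[pos, config$effect_mask] <- M[pos, config$effect_mask] - delta
        }
        rownames(M) <- subjects$subject_id
        volumes[[tp]][[ch]] <- M
      }
      S <- matrix(stats::rnorm(n * config$n_scores), nrow = n)
      if (length(informative) > 0L && config$score_effect_d != 0) {
        S[pos, informative] <- S[pos, informative] + config$score_effect_d
      }
      colnames(S) <- sprintf("score%02d", seq_len(config$n_scores))
      rownames(S) <- subjects$subject_id
      scores[[tp]] <- S
    }
    structure(
      list(subjects = subjects,
           volumes = volumes,
           scores = scores,
           grid = list(shape = config$grid_shape,
                       voxel_size_mm = config$voxel_size_mm),
           config = config,
           truth = list(effect_mask = config$effect_mask,
                        informative_scores = informative)),
      class = "cohort_bundle"
    )
  })
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf(
    "<cohort_bundle> %d subjects (%d per class), %d timepoints, grid %s, %d scores\n",
    nrow(x$subjects), x$config$n_per_class, length(x$config$timepoints),
    paste(x$grid$shape, collapse = "x"), x$config$n_scores))
  invisible(x)
}

#' Extract one subject's volume as a `volume_grid`
#'
#' @param bundle a [generate_cohort()] result.
#' @param subject_id subject identifier.
#' @param timepoint,channel which volume.
#' @return a [volume_grid()].
#' @export
get_volume <- function(bundle, subject_id, timepoint, channel) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  M <- bundle$volumes[[timepoint]][[channel]]
  if (is.null(M)) stop_arg("no volume for timepoint/channel ",
                           timepoint, "/", channel)
  if (!subject_id %in% rownames(M)) stop_arg("unknown subject ", subject_id)
  volume_grid(array(M[subject_id, ], dim = bundle$grid$shape),
              voxel_size_mm = bundle$grid$voxel_size_mm,
              channel = channel)
}

#' Randomly permute the diagnostic labels of a cohort
#'
#' Reassigns the subjects' group/binary labels by a random permutation,
#' leaving volumes and scores untouched — the null-hypothesis cohort used by
#' the permutation test.
#'
#' @param bundle a `cohort_bundle`.
#' @param seed integer seed for the permutation draw.
#' @return a `cohort_bundle` with permuted labels.
#' @export
permute_labels <- function(bundle, seed) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  perm <- with_rng(seed, sample.int(nrow(bundle$subjects)))
  bundle$subjects$group <- bundle$subjects$group[perm]
  bundle$subjects$binary_label <- bundle$subjects$binary_label[perm]
  bundle
}

#' Serialize a cohort to NIfTI + CSV files
#'
#' Writes one NIfTI volume per (subject, timepoint, channel), a long-format
#' `scores.csv` (`subject_id`, `group`, `timepoint`, score columns), a
#' `subjects.csv` label table, and a JSON `manifest.json` listing every file
#' plus the grid geometry. [read_cohort()] on the manifest reproduces the
#' bundle's volumes and scores exactly.
#'
#' @param bundle a `cohort_bundle`.
#' @param directory output directory (created if missing).
#' @return path to the manifest, invisibly.
#' @export
write_cohort <- function(bundle, directory) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE,
                                            showWarnings = FALSE)
  voldir <- file.path(directory, "volumes")
  ok <- ok && (dir.exists(voldir) || dir.create(voldir, showWarnings = FALSE))
  if (!ok || file.access(directory, mode = 2L) != 0L) {
    stop_arg("directory not writable: ", directory)
  }
  files <- character(0)
  for (tp in names(bundle$volumes)) {
    for (ch in names(bundle$volumes[[tp]])) {
      M <- bundle$volumes[[tp]][[ch]]
      for (sid in rownames(M)) {
        f <- file.path("volumes", sprintf("%s_%s_%s.nii.gz", sid, tp, ch))
        write_volume(
          volume_grid(array(M[sid, ], dim = bundle$grid$shape),
                      voxel_size_mm = bundle$grid$voxel_size_mm,
                      channel = ch),
          file.path(directory, f))
        files <- c(files, f)
      }
    }
  }
  scores_long <- do.call(rbind, lapply(names(bundle$scores), function(tp) {
    data.frame(subject_id = rownames(bundle$scores[[tp]]),
               group = bundle$subjects$group,
               timepoint = tp,
               bundle$scores[[tp]],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  utils::write.csv(scores_long, file.path(directory, "scores.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$subjects, file.path(directory, "subjects.csv"),
                   row.names = FALSE)
  manifest <- list(
    grid_shape = bundle$grid$shape,
    voxel_size_mm = bundle$grid$voxel_size_mm,
    timepoints = bundle$config$timepoints,
    channels = names(bundle$volumes[[1L]]),
    n_scores = bundle$config$n_scores,
    subjects_csv = "subjects.csv",
    scores_csv = "scores.csv",
    volumes = files,
    truth = bundle$truth
  )
  manifest_path <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest_path)
}

#' Read a cohort back from a manifest
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [write_cohort()].
#' @return a `cohort_bundle` (without the generating `config`; the `truth`
#'   block is restored from the manifest).
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop_arg("no manifest at ", manifest_path)
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  root <- dirname(manifest_path)
  subjects <- utils::read.csv(file.path(root, m$subjects_csv),
                              stringsAsFactors = FALSE)
  scores_long <- utils::read.csv(file.path(root, m$scores_csv),
                                 stringsAsFactors = FALSE)
  shape <- as.integer(m$grid_shape)
  V <- prod(shape)
  volumes <- list()
  for (tp in m$timepoints) {
    volumes[[tp]] <- list()
    for (ch in m$channels) {
      M <- matrix(NA_real_, nrow(subjects), V,
                  dimnames = list(subjects$subject_id, NULL))
      for (sid in subjects$subject_id) {
        f <- file.path(root, "volumes",
                       sprintf("%s_%s_%s.nii.gz", sid, tp, ch))
        M[sid, ] <- as.numeric(read_volume(f, channel = ch)$intensities)
      }
      volumes[[tp]][[ch]] <- M
    }
  }
  score_cols <- setdiff(names(scores_long), c("subject_id", "group", "timepoint"))
  scores <- list()
  for (tp in m$timepoints) {
    block <- scores_long[scores_long$timepoint == tp, , drop = FALSE]
    S <- as.matrix(block[, score_cols, drop = FALSE])
    rownames(S) <- block$subject_id
    S <- S[subjects$subject_id, , drop = FALSE]
    scores[[tp]] <- S
  }
  structure(
    list(subjects = subjects,
         volumes = volumes,
         scores = scores,
         grid = list(shape = shape, voxel_size_mm = as.numeric(m$voxel_size_mm)),
         config = NULL,
         truth = list(effect_mask = as.integer(m$truth$effect_mask),
                      informative_scores = as.integer(m$truth$informative_scores))),
    class = "cohort_bundle"
  )
}
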