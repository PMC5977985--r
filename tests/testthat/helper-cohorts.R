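# Small cohort builders shared across tests. All fixtures are generated in
# code; sizes are desk-scale so the suite stays fast.

SMALL_SHAPE <- c(12L, 14L, 12L)

# Tiny null cohort (no planted effects), scores only matter: used for
# permutation calibration studies.
null_scores_cohort <- function(seed = 42) {
  generate_cohort(cohort_config(
    n_per_class = 20, grid_shape = c(4, 4, 4),
    timepoints = "t0", effect_delta_by_timepoint = c(t0 = 0),
    base_smooth_fwhm_mm = 0, n_scores = 6, n_informative_scores = 0,
    seed = seed))
}

# Strongly separable cohort: large planted GM decrement and strong score
# effect, with an effect region larger than a top-decile of the grid.
separable_cohort <- function(seed = 1, n_per_class = 50) {
  generate_cohort(cohort_config(
    n_per_class = n_per_class, grid_shape = SMALL_SHAPE,
    timepoints = "t0",
    effect_mask = sphere_mask(SMALL_SHAPE, radius = 4),
    effect_delta_by_timepoint = c(t0 = 5),
    noise_sd = 1, base_smooth_fwhm_mm = 4,
    n_scores = 16, n_informative_scores = 3, score_effect_d = 2,
    seed = seed))
}

small_grid <- function(...) {
  default_grid(channels = "GM", fwhm_mm = c(0, 4), k_mri = c(2, 5),
               k_np = c(0, 2), ...)
}

local_tempdir <- function(env = parent.frame()) {
  path <- tempfile("mcipredict-test-")
  dir.create(path)
  do.call(on.exit, list(bquote(unlink(.(path), recursive = TRUE)), add = TRUE),
          envir = env)
  path
}
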