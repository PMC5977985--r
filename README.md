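# mcipredict

Multimodal machine-learning prediction of conversion to Alzheimer's
dementia from structural MRI and neuropsychological testing.

Only about a third of subjects with mild cognitive impairment (MCI) progress
to Alzheimer's dementia, and trials that enroll on clinical grounds alone
dilute their cohorts with subjects who were never going to convert.
`mcipredict` implements, as a tested R package plus analysis workflow, a
classifier pipeline that separates subjects on a path to dementia
(progressive MCI + AD) from cognitively stable subjects (controls + stable
MCI) at longitudinal time points *before* the diagnosis is definite, using
registered structural brain volumes (whole-brain, gray-matter and
white-matter probability maps) together with neuropsychological scores and
sub-scores. It is aimed at neuroimaging methodologists who want a fully
reproducible, leakage-audited reference implementation of this class of
pipeline, exercised end to end on synthetic cohorts with known ground truth
(no data download required).

## The method

For each time point and modality:

* **Features.** Voxel vectors from the selected tissue channel, smoothed by
  an isotropic Gaussian (FWHM ∈ {none, 2, 4, …, 12} mm,
  σ = FWHM / (2√(2 ln 2))), are reduced by PCA fitted on training data only
  (at most *S* − 1 coefficients for *S* training samples; 199 for a
  200-subject cohort) or, alternatively, by PLS. Neuropsychological scores
  are z-score normalized with training statistics. Both streams are ranked
  by the Fisher discriminant ratio

  FDR = (μ_A − μ_B)² / (σ_A² + σ_B²),

  with sample variances per class.
* **Classifier.** A soft-margin linear SVM,
  y(x) = Σₙ wₙ tₙ ⟨x, xₙ⟩ + b, positive side = progressive class.
* **Selection and evaluation.** Fivefold nested cross-validation: inner
  folds (wrapper) choose tissue channel, FWHM and the number of retained
  MRI/score features by validation accuracy; outer folds estimate accuracy,
  sensitivity and specificity (mean ± sd over 5 rounds). With 200 balanced
  subjects every round trains on 128, validates on 32 and tests on 40.
* **Inference.** Label-permutation testing of the whole pipeline
  (p = fraction of permuted runs ≥ observed), one-way ANOVA across time
  points, paired t-tests between matched configurations.
* **Interpretation.** Per-fold SVM weights are corrected to activation
  patterns (Cov(X)·w), back-projected to voxels through the PCA loadings,
  fold-averaged, normalized to [0, 1] and thresholded at 35%; selected
  neuropsychological scores are tabulated by selection frequency with a 5%
  cutoff.

The synthetic cohort generator plants a growing gray-matter intensity
decrement inside a known voxel region and a known subset of informative
scores, so calibration (chance-level behavior under label shuffling) and
recovery (region and score identification) are verifiable properties, not
hopes. See `vignettes/multimodal-prediction-methods.Rmd` for the full
methods account.

## Worked example

```r
library(mcipredict)

# a 100-subject cohort with a strong planted GM effect and 3 informative scores
cfg <- cohort_config(
  n_per_class = 50, grid_shape = c(12, 14, 12), timepoints = "t0",
  effect_mask = sphere_mask(c(12, 14, 12), radius = 4),
  effect_delta_by_timepoint = c(t0 = 5),
  n_scores = 16, n_informative_scores = 3, score_effect_d = 2, seed = 1)
bundle <- generate_cohort(cfg)

grid <- default_grid(channels = c("whole_brain", "GM"), fwhm_mm = c(0, 4),
                     k_mri = c(2, 5, 10), k_np = c(3, 8))
fit <- run_nested_cv(bundle, "t0", modality = "mri_plus_np",
                     extractor = "pca_fdr", grid = grid, seed = 1)
fit
#> <performance_summary> t0 / mri_plus_np / pca_fdr (5x5 nested CV)
#>   accuracy    1.000 +/- 0.000
#>   sensitivity 1.000 +/- 0.000
#>   specificity 1.000 +/- 0.000

fit$folds[[1]]$chosen
#>   channel fwhm_mm k_mri k_np extractor
#> 1      GM       0     2    3   pca_fdr

im <- importance_map(fit, bundle$grid$shape)
top <- order(-as.numeric(im$values))[1:round(0.1 * length(im$values))]
mean(top %in% bundle$truth$effect_mask)
#> [1] 1

head(np_predictor_frequency(fit, universe = colnames(bundle$scores$t0)), 5)
#>      name frequency flagged
#> 1 score04         1    TRUE
#> 2 score07         1    TRUE
#> 3 score09         1    TRUE
#> 4 score01         0   FALSE
#> 5 score02         0   FALSE
```

The wrapper finds the planted structure on its own: every round picks the
GM channel (where the effect lives) and a small feature set; the cohort is
perfectly classified; all of the top-decile importance voxels fall inside
the planted region; and exactly the three planted scores are selected in
every round (frequency 1), with all others at 0.

The numbered scripts under `analysis/` run the full study on the
200-subject reference cohort: `01` characterizes the planted effects, `02`
produces the performance table per time point × modality, `03` compares
extractors and time points, `04` runs the permutation test, `05` exports
the importance map and predictor frequency table. Outputs land in
`results/`.

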