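---
title: "Methods: multimodal nested-CV prediction of conversion to Alzheimer's dementia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal nested-CV prediction of conversion to Alzheimer's dementia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Only a minority of subjects with mild cognitive impairment (MCI) progress to
Alzheimer's dementia, and neither clinical judgement nor any single score
reliably identifies, months to years in advance, who will. `mcipredict`
implements a machine-learning pipeline that separates subjects on a path to
dementia (progressive MCI and AD, the positive class, label +1) from
cognitively stable subjects (controls and stable MCI, label -1) at
longitudinal time points before the diagnosis becomes definite. The inputs
are structural brain volumes that are already registered to a common space
(whole-brain image plus gray- and white-matter probability maps) and a table
of neuropsychological scores and sub-scores; the reference study design uses
200 subjects (100 per class), four time points (24, 18 and 12 months before
stable diagnosis, plus the stable-diagnosis point `t0`) and 64 scores from
seven standard tests.

The package is organized as an analysis workflow: every computation lives in
package functions; the numbered scripts under `analysis/` are thin narrative
drivers that run the experiments on synthetic cohorts and write result
tables.

## The model and the pipeline

For each time point and modality the pipeline is:

1. **Preprocessing choices searched by the wrapper.** Tissue channel
   (whole-brain, GM or WM) and isotropic Gaussian smoothing FWHM from
   \{none, 2, 4, ..., 12\} mm. Smoothing uses per-axis
   $\sigma_\text{vox} = \mathrm{FWHM} / (2\sqrt{2\ln 2}) / \text{voxel size}$,
   a unit-sum discrete kernel and reflecting boundaries (which conserve
   total intensity on small grids, unlike zero padding). Voxels are
   flattened in a fixed, documented order (R column-major: first axis
   fastest), so feature $j$ is the same voxel for every subject and
   importance maps can be folded back into the grid.
2. **Feature extraction.** PCA fitted on the training rows only: at most
   $S - 1$ components for $S$ training samples carry variance, so a
   200-subject cohort yields at most 199 coefficients. A PLS variant
   (projection directions maximizing covariance with the labels, computed
   by iterative deflation) is available as an independent extractor; its
   component count plays the role of `k_mri`.
3. **Ranking.** MRI coefficients and z-scored neuropsychological scores are
   each ranked by the Fisher discriminant ratio
   $\mathrm{FDR} = (\mu_A - \mu_B)^2 / (\sigma_A^2 + \sigma_B^2)$
   (sample variances, $n-1$). A zero denominator with a non-zero numerator
   is treated as $+\infty$ (such a feature separates the classes
   perfectly); ties keep the original column order. PLS components are used
   in their natural order instead of being re-ranked.
4. **Classification.** A soft-margin linear SVM,
   $y(x) = \sum_n w_n t_n \langle x, x_n\rangle + b$, with fixed cost
   $C = 1$ (the wrapper searches features and preprocessing, not $C$). The
   positive decision side is the progressive class, so sensitivity is the
   detection rate of subjects who will convert.
5. **Wrapper selection in fivefold nested CV.** The cohort is split into 5
   stratified outer folds; within each outer training portion (4/5 of the
   cohort), 5 stratified inner folds choose — by mean validation accuracy —
   the channel, FWHM, `k_mri` and `k_np`. The chosen configuration is refit
   on the whole outer training portion and evaluated once on the untouched
   outer test fold. With 200 balanced subjects this gives 128 training, 32
   validation and 40 test subjects per round. Reported numbers are fold
   means $\pm$ sd ($n-1$).

Significance of a performance metric is assessed by a permutation test:
the diagnostic labels are randomly permuted and the *complete* pipeline —
including inner selection — is rerun; the p-value is the fraction of
permuted runs whose metric is greater than or equal to the observed one
(resolution $1/n_\text{iter}$; the reference design uses 1000 iterations,
and an add-one smoothed estimator is available behind a flag). Rerunning
selection inside every iteration keeps selection-induced optimism in the
null, which is the conservative choice. Performance across time points is
compared by one-way fixed-effects ANOVA on the fold metrics, and matched
configurations (PCA+FDR vs. PLS, MRI-only vs. multimodal) by two-sided
paired t-tests on the fold differences.

## Interpretation artifacts

For runs using the PCA+FDR extractor, the per-fold linear-SVM weight vector
is converted to its forward-model counterpart
$A = \mathrm{Cov}(X_\text{train})\,w$ (the activation pattern of the
backward model) in the trained feature space, the MRI part is back-projected
to voxels through the fold's PCA loadings, and the per-fold voxel maps are
averaged — as magnitudes, so opposing fold signs cannot cancel a
discriminative voxel; a signed variant is available. The average is min-max
normalized to $[0, 1]$ and a display threshold (default 0.35) zeroes
sub-threshold voxels in the exported thresholded variant. The correction is
applied per fold, before averaging, following the order in which the
procedure is described in the field. Neuropsychological predictors are
summarized by selection frequency across the 5 rounds; scores above the 5%
cutoff are flagged as best predictors (with 5 rounds this is equivalent to
"selected at least once", but the cutoff semantics are kept for larger
round counts).

## The synthetic cohort generator

Real cohorts of this design cannot ship with a package, so
`generate_cohort()` produces longitudinal cohorts with known ground truth
that emulate the statistical structure the analysis assumes — and nothing
more. Defaults mirror the reference design: 100 subjects per class, four
time points, three channels, 64 scores.

* **Volumes** are Gaussian noise (sd 1) on a 20×24×20 grid of 2 mm voxels,
  smoothed to an intrinsic 4 mm FWHM. The grid is desk-scale while
  preserving genuine 3D smoothing behavior; any congruent grid is accepted
  by the pipeline.
* **The group effect** is a mean intensity decrement (an atrophy surrogate)
  inside a spherical voxel mask, planted only in the GM channel so the
  wrapper's tissue-map choice has a recoverable truth. It is subtracted
  *after* the intrinsic smoothing, so the planted contrast equals
  `effect_delta` exactly and the empirical standardized group difference is
  monotone in it. Deformation, anatomy, scanner artifacts and site effects
  are deliberately not modeled: the pipeline consumes intensities after
  segmentation and smoothing, so an intensity effect exercises every
  downstream stage.
* **Effect sizes** default to decrements ramping from 0.12 to 0.24 noise-sd
  units across the four time points. Relative to the intrinsically smoothed
  noise this yields moderate voxelwise standardized differences (roughly
  0.5–1), the scale typically reported for gray-matter group differences in
  prodromal disease, and it keeps the default cohort neither trivial nor
  hopeless for the classifier.
* **Scores**: 8 of the 64 columns (by default) are shifted by 0.8 pooled
  standard deviations in the positive class — a strong-but-plausible
  neuropsychological effect — while the remaining columns are pure noise.
* Everything is a deterministic function of the configuration (bit-identical
  across calls and processes given the same seed).

What passing tests on these cohorts shows: the machinery selects, fits,
evaluates and localizes without information leakage, is calibrated at
chance under the null, and recovers planted structure when it is present.
What it does not show: performance levels on real MRI, where effects are
spatially diffuse, covary with age and sex, and are entangled with
registration and segmentation error. Performance on a real cohort depends
on the accessed data and cannot be inferred from synthetic numbers.

## Numerical choices and degenerate inputs

* PCA loadings get a deterministic sign (largest-magnitude entry positive);
  eigenvector signs are otherwise arbitrary and would break reproducibility.
* PCA, PLS, z-scoring and FDR ranking are fitted strictly inside each
  training partition; the fitted projections are then applied to the whole
  cohort matrix (a row-wise operation, so nothing leaks) and rows are
  indexed per fold — this is the package's main computational optimization.
* Wrapper ties are broken toward the simpler model: smaller `k_mri`, then
  smaller `k_np`, then smaller FWHM, then channel order whole-brain < GM <
  WM.
* The SVM QP (libsvm via e1071) runs at termination tolerance `1e-6`;
  decisions of exactly 0 map to the positive class. A constant score column
  z-scores to all zeros with a warning; an all-constant importance map
  normalizes to zeros with a warning; a paired test with all-zero
  differences reports statistic 0 and p = 1; an all-constant ANOVA reports
  F = 0 and p = 1.
* Permutation iterations derive their seeds from the master seed by a
  counter, so they are reproducible and independent of evaluation order.

## Problem sizes used in the shipped experiments

The analysis scripts and the test suite run the full pipeline on cohorts of
30–200 subjects with grids from 12×14×12 to the default 20×24×20, wrapper
grids of 10–50 points, and permutation tests of 19–99 iterations (with the
1000-iteration reference design documented above). These sizes were chosen
so a complete desk run finishes in minutes while every structural property
of the full design — fold sizes 128/32/40, the 199-component bound, the
calibration and recovery behavior — is exercised at full fidelity.

## Known limitations

* The synthetic generator does not emulate age/sex matching covariates;
  no implemented computation consumes them.
* MRI importance maps are only defined for the PCA+FDR extractor (the PLS
  back-projection would require the deflation loadings' pseudo-inverse and
  is not part of the reference procedure).
* With five outer rounds the predictor-frequency cutoff of 5% flags any
  score selected at least once; interpret flags accordingly.
* The permutation p-value has resolution `1/n_iter`; at desk-scale
  iteration counts a "significant" result means "no permuted run did as
  well", not a finely resolved tail probability.
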