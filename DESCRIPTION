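Package: mcipredict
Title: Multimodal MRI and Neuropsychological Prediction of Conversion to
    Alzheimer's Dementia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nested cross-validation machine-learning pipeline that
    discriminates subjects on a path to Alzheimer's dementia (progressive
    MCI and AD) from cognitively stable subjects (controls and stable MCI)
    at longitudinal time points before definite diagnosis, from structural
    MRI volumes combined with neuropsychological test scores. Implements
    Fisher-discriminant-ratio feature ranking, PCA and PLS feature
    extraction, wrapper selection of features and preprocessing parameters
    (tissue map, smoothing FWHM) inside a fivefold nested cross-validation,
    permutation significance testing of classifier performance, and
    interpretation artifacts: activation-pattern-corrected voxel importance
    maps and neuropsychological predictor frequency tables. Ships a
    synthetic longitudinal cohort generator with known ground truth so the
    whole pipeline runs end to end without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
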