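Package: mvpasvr
Title: Predicting Individual Outcomes from Time-Averaged Voxel Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Multi-voxel pattern analysis (MVPA) of time-averaged
    T2*-weighted MRI signal for predicting per-subject behavioural
    outcomes such as training-induced score improvement. Provides a
    synthetic cohort generator with known ground truth, volume
    normalization and temporal averaging, consensus tissue segmentation,
    ROI feature extraction, a from-scratch linear epsilon-insensitive
    support vector regression solved by pairwise dual ascent,
    leave-one-subject-out cross-validation, and the surrounding
    correlation statistics (Fisher z inference, correlation comparison,
    second-order partial correlations, median-split group tests, and a
    spatial-mean baseline).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    kernlab,
    yaml
Config/testthat/edition: 3
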