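Package: fcmvpa
Title: Whole-Brain Functional Connectivity Group Analysis with Multivariate
    Pattern Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for case-control resting-state functional
    connectivity studies on a 90-region anatomical parcellation. Computes
    Fisher r-to-z edge vectors from ROI time series, runs edgewise univariate
    statistics with Bonferroni, Benjamini-Hochberg and network-based-statistic
    (NBS) multiple-comparison control, performs leave-one-subject-out linear
    SVM classification with nested F-score feature selection and a
    max-over-grid permutation test for family-wise error control, and
    characterizes the selected connections (weighted degrees, intra- and
    inter-network standardized percentages, clinical correlations). Includes a
    synthetic cohort generator with controllable group effects for calibration
    and power testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    igraph,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
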