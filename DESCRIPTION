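Package: netcog
Title: Brain Network Topology Features and Whale-Optimized Kernel
    Regression for Cognitive-Score Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Predicts clinical cognition scores from resting-state brain
    functional networks. Builds subject connectomes from ROI time series
    (Pearson correlation, Fisher-Z transform, sparsity-threshold
    binarization), extracts areas under the curve of seven global
    topological metrics across a sparsity grid, selects features by
    PCA-based variance weighting, and fits a least-squares support-vector
    regressor whose kernel hyperparameters are tuned by a whale
    optimization algorithm with Levy-flight steps. Includes a synthetic
    two-group cohort generator with a known score link, a stratified
    cross-validation harness for comparing framework variants, and
    group-level statistics (feature comparisons, node-efficiency score
    associations).
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    e1071,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
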