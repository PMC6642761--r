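Package: dppca
Title: Douglas-Peucker and PCA Feature Extraction for Multichannel EEG Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and evaluation pipeline for multicategory EEG
    seizure detection. Multichannel recordings are split into fixed-size
    nonoverlapping time windows, the most representative time points of each
    window are retained with the Douglas-Peucker polyline simplification
    algorithm under an adaptive, path-length-based tolerance, and the retained
    samples are projected onto principal components selected by a cumulative
    eigenvalue criterion. A stratified k-fold cross-validation harness with
    pluggable classifier backends (random forest, k-nearest neighbour,
    polynomial-kernel SVM, decision tree) evaluates the resulting features
    with per-class sensitivity, specificity, false positive rate, overall
    accuracy, Cohen's kappa and one-vs-rest AUC. A seeded synthetic EEG
    generator provides labelled multichannel test data with class-distinct
    amplitude and spectral content and correlated channels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    randomForest,
    class,
    e1071,
    rpart
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
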