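Package: swnet
Title: Shared-Weight Autoencoder and 1-D CNN Pipeline for Functional
    Connectivity Classification
Version: 0.1.0
Authors@R:
    person("swnet", "maintainers", email = "swnet@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying subjects from resting-state functional
    connectivity features. Implements Pearson functional-connectivity
    feature extraction with upper-triangle vectorization and recursive
    feature elimination, an EROS (extended Frobenius norm) distance over
    multivariate ROI time series driving SMOTE-style nearest-neighbour
    data augmentation, a Gaussian-noise denoising autoencoder for
    unsupervised pretraining, a bespoke one-dimensional convolutional
    network whose input stage shares the pretrained encoder weights, and
    evaluation protocols (nested k-fold, leave-one-out and
    leave-one-site-out cross-validation) with a leakage guard. A
    synthetic-cohort generator produces two-class multivariate Gaussian
    time series with controlled between-class correlation differences so
    the whole pipeline is testable without any neuroimaging download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
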