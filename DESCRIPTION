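Package: equivnet
Title: Rotation-Equivariant Convolutional Classifiers for Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Group-equivariant convolutional neural networks for classifying
    microscopy images whose labels are invariant to the orientation of the
    sample under the instrument. Implements exact (interpolation-free) p4 and
    p4m group algebra on square pixel grids, lifting and group convolutions
    with group pooling, paired baseline/equivariant VGG16-style classifier
    builders with parameter accounting, a deterministic training loop with
    convergence (stable-accuracy) metrics, a synthetic generator of
    rotation-invariant labelled image datasets with orbit augmentation,
    class rebalancing, nested subsampling and stratified cross-validation
    folds, and evaluation utilities including confusion-matrix summaries and
    power-law data-efficiency fits by log-log regression.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    tiff,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
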