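Package: spotsight
Title: Inferring Spatial Gene Expression at Visium Spots from Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for predicting spatially resolved gene expression at
    Visium capture spots from co-registered slide images, and for testing
    whether the inferred expression recapitulates spatial biology. The
    package provides a synthetic Visium-like slide simulator with known
    ground truth (hexagonal spot lattice, zero-inflated negative binomial
    counts, image textures encoding local and neighborhood signal), a small
    trainable convolutional patch model and a graph attention network over
    the spot adjacency graph (both with dichotomized-expression and
    zero-inflated negative binomial objectives), leave-one-slide-out
    cross-validation with per-gene AUROC/AP/correlation metrics and
    bootstrap confidence intervals, permutation Moran's I tests for
    spatially variable genes, a smoothing-based fraction-of-spatial-variance
    estimator, spatial co-expression grouping, and threshold-optimized
    Fisher's exact recapitulation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
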