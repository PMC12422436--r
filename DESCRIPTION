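Package: spermdfe
Title: Attention-Augmented Residual Networks and Deep Feature Engineering
    for Sperm Morphology Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a convolutional block attention module (CBAM)
    enhanced residual network together with a deep feature engineering
    pipeline for sperm-head morphology classification. Provides a seeded
    synthetic microscope-image generator (3-class and 4-class schemes),
    an enhance/denoise/sharpen preprocessing chain, a from-scratch
    residual backbone with channel and spatial attention and two-stage
    Adam training, multi-site deep feature extraction (CBAM, global
    average pooling, global max pooling, pre-final), ten feature
    selection strategies (PCA, chi-square, random-forest importance,
    variance, and their pairwise intersections), shallow classification
    with support vector machines and k-nearest neighbours over a
    cross-validated configuration grid, confusion-matrix metrics with
    McNemar's paired test, and Grad-CAM / 2-D embedding explainability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    grDevices,
    graphics,
    jsonlite,
    png,
    ranger,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Rtsne,
    jpeg,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
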