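Package: zebrascreen
Title: Automatic Phenotype Classification of Zebrafish Larvae from
    Brightfield Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised classification of brightfield images of zebrafish
    larvae into morphological phenotype classes, and toxicological readout of
    classified plates. Implements larva localization and square cropping by
    morphological operators, random-subwindow extraction with per-channel
    TRGB standardization, extremely randomized trees with pixel-level node
    tests (single-pixel thresholding and neighbor-difference tests), image
    classification by direct subwindow voting or by bag-of-leaf-frequency
    descriptors with a linear SVM, a two-tier Chorion/Dead/Others gate
    followed by per-defect binary models with confusion carry-over
    correction, randomized cross-validation for hyperparameter tuning,
    four-parameter log-logistic dose-response fitting (LC50, EC50,
    teratogenicity index), and a parametric synthetic larva-image generator
    with exact ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    e1071,
    jsonlite,
    minpack.lm,
    png,
    Rcpp,
    stats,
    tiff,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
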