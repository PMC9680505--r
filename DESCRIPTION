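Package: canopyseg
Title: Two-Stage Segmentation of Canopy Images into Background, Green and
    Senescent Vegetation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for segmenting high-resolution RGB images of crop canopies
    into background, green vegetation and senescent vegetation. A miniature
    trainable encoder-decoder network separates vegetation from background;
    a support vector machine operating on 23 colour-space features then
    splits vegetation pixels into green and senescent. The package also
    provides sequential forward feature selection, leave-one-out
    hyperparameter tuning, sparse grid-pixel annotation handling with a
    six-label schema, weak-supervision training of a direct three-class
    network on pseudo-masks, the full evaluation toolkit (per-class
    precision/recall/F1, confidence intervals, canopy fractions, fraction
    regression, model-agreement matrices, misclassification colour
    profiling), an RGB colour-cube mapper, and a synthetic canopy scene
    generator with exact ground truth for testing everything at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    png,
    Rcpp,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
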