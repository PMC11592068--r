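Package: ucapsnet
Title: Two-Stage Breast Ultrasound Lesion Segmentation and Capsule Network Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage analysis pipeline for grayscale breast ultrasound
    images. Stage one segments lesions with an enhanced U-Net (encoder-decoder
    with skip connections, batch normalization and dropout); stage two
    classifies the predicted binary masks as benign or malignant with a
    capsule network (dense-block feature extractor, primary capsules with
    squash nonlinearity, dynamic routing by agreement, margin loss). Includes
    a seeded synthetic speckle-phantom generator so the whole pipeline can be
    trained and evaluated without external data, readers for BUSI-style PNG
    dataset layouts, and segmentation/classification metrics (Dice, IoU,
    confusion-matrix reports) with stratified k-fold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
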