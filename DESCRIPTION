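Package: her2lite
Title: Lightweight Attention and Pruned Convolutional Networks for HER2 Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains and explains two lightweight convolutional
    networks for HER2 immunohistochemistry scoring of breast-cancer
    histopathology patches: ATHER2, a two-branch network with a
    convolutional block attention module (CBAM), and PrunEff, a family of
    block-pruned EfficientNetV2B0 subnetworks. Includes a seedable CNN
    runtime with backpropagation and Adam, plateau learning-rate
    scheduling, early stopping and image augmentation; transfer-learning
    and domain-specific pretraining workflows; HER2 label groupings with a
    full metric suite (accuracy, precision, recall, F1, AUC, Matthews
    correlation); Grad-CAM heatmaps with a quantitative localization
    score; and a class-conditional synthetic IHC/H&E patch generator with
    ground-truth membrane masks and patient-wise splits for desk-scale
    experimentation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
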