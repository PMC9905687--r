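Package: uavpn
Title: Estimating Rice Canopy Net Photosynthesis from UAV Multispectral Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for estimating rice canopy net
    photosynthetic rate (Pn, umol m-2 s-1) from five-band (blue, green, red,
    red-edge, near-infrared) UAV multispectral imagery. Provides a seeded
    synthetic field-trial generator emulating a two-factor (nitrogen x
    leakage) paddy experiment over three growth stages; reflectance
    extraction (radiometric gain/offset, background masking, quadrat ROI
    averaging); a 25-index vegetation-index library; moving-window
    gray-level co-occurrence matrix (GLCM) texture features (8 features x 5
    bands); normalized-difference / difference / renormalized-difference
    texture-index pair search; Pearson-correlation feature selection with
    significance testing; and comparison of five regression models (linear
    regression, support vector regression, gradient-boosted trees, random
    forest, multilayer perceptron) under 10-fold cross-validation across
    three feature-fusion regimes (vegetation indices; + texture indices;
    + plant height and SPAD).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    e1071,
    generics,
    ggplot2,
    nnet,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    xgboost,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
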