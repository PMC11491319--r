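Package: lungcbo
Title: Lung CT Nodule Analysis with Colliding Bodies Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end toolkit for lung computed-tomography nodule
    analysis on 2-D grayscale slices: synthetic lung phantom generation with
    ground-truth nodule masks, histogram-equalization and median-filter
    preprocessing, multilevel Otsu thresholding driven by the Colliding
    Bodies Optimization (CBO) metaheuristic, nodule localization via
    connected components, local binary pattern (LBP) texture features, a
    small densely connected convolutional network (DenseNet-style) for
    benign/malignant classification, confusion-matrix and ROC evaluation,
    and a ThingSpeak-style IoT channel-update adapter with a mock transport.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    igraph,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
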