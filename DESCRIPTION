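Package: sknspace
Title: Hybrid Color Spaces for Pixel-Wise Skin Detection
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives low-dimensional hybrid color spaces for pixel-wise skin
    segmentation. Builds a 32-component pixel feature matrix from seventeen
    conventional color-space transforms, selects a discriminative component
    subset with a genetic-algorithm wrapper driven by cross-validated random
    forest F-score, and projects the selected components onto their leading
    principal components to obtain a compact hybrid space. Ships the published
    three-channel SKN transform as a canonical built-in, pluggable pixel
    classifiers (random forest, kernel naive Bayes, polynomial-kernel SVM,
    multilayer perceptron), ROC/F-score evaluation utilities, a seeded
    synthetic scene generator for reproducible benchmarking, and a command
    line interface tying the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    methods,
    jsonlite,
    yaml,
    png,
    quadprog,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    jpeg,
    pixmap,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
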