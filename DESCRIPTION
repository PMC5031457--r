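Package: callforest
Title: Optimum-Path Forest Classification of Marmoset Vocalizations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for classifying common-marmoset
    (Callithrix jacchus) call types from audio: band-pass filtering and
    amplitude-threshold segmentation of 44.1 kHz recordings, linear
    predictive coding (LPC) feature extraction via the Levinson-Durbin
    recursion, a from-scratch supervised Optimum-Path Forest (OPF)
    classifier with five distance metrics, adapters for six comparison
    classifiers, class-balanced evaluation metrics, repeated stratified
    train/test experiment protocols including hierarchical sub-class
    classification with compounded accuracies, and a deterministic
    synthetic-call generator so the whole pipeline is testable without
    audio downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    rlang,
    rpart,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
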