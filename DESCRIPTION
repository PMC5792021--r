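Package: triview
Title: Multi-View Ensemble Classification of Specimen Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying insect specimens (e.g. ant genera) from the
    three standard photographic views of a mounted specimen: head, dorsum and
    profile. Provides a multi-view dataset model with manifest I/O,
    minimum-support label filtering and a stratified train/validation/test
    split; a parametric synthetic-image generator with controllable per-view
    informativeness; a declarative convolutional-network architecture calculus
    (layer output-size formula, reference 12-layer network, scaled variants);
    three training regimes (general-purpose over pooled views, view-specific,
    and transfer fine-tuning warm-started from the general model) with
    validation-monitored checkpoint selection on a compact built-in CNN
    engine; top-t evaluation metrics (accuracy, macro-average and minimum
    per-label precision); pairwise double-fault diversity measures; and
    softmax-sum score fusion across views and regimes into G/S/T/All
    ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
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
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
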