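Package: hrvtda
Title: Topological Persistence Statistics for Heart Rate Variability and
    Sleep Staging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyzes instantaneous-heart-rate time series with persistent
    homology.  Computes persistence diagrams of 90-second heart-rate windows
    through two filtrations (the sub-level set filtration of the series and
    the Vietoris-Rips filtration of its Takens delay embedding), summarizes
    each diagram with sixteen persistence statistics (moments, quartiles and
    persistent entropy of the midpoint and lifespan multisets), and
    classifies sleep stages (wake/sleep, REM/NREM, wake/REM/NREM) from the
    resulting 48-dimensional feature vectors with a class-balanced linear
    support vector machine.  Includes a general Z2 persistence engine with
    bottleneck distance for validation, a synthetic polysomnography-like
    R-peak generator so the whole pipeline runs without clinical data, and
    the full evaluation suite (sensitivity, positive predictivity, F1,
    accuracy, Cohen's kappa, AUC, rank-sum feature screening).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
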