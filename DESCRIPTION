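Package: ihctriage
Title: Confidence-Aware Multilabel Classification and Triage of Immunohistochemistry Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid Bayesian neural network (HBNet) workflow for multilabel
    cell-type classification of immunohistochemistry (IHC) images, with
    confidence-aware triage. Combines handcrafted texture descriptors
    (histogram of oriented gradients, Haralick co-occurrence statistics, Hu
    moments, reduced by PCA) with learned convolutional features, trains a
    Drop-Weights network by backpropagation, and approximates the Bayesian
    posterior by Monte-Carlo sampling of weight masks at inference time.
    Per-label predictive means are summarised into jackknife bias-corrected
    entropies, the class predictive probability distance (CPPD) and the DHC
    confidence score, which ranks predictions for automated acceptance versus
    manual review. Includes multilabel evaluation metrics, MCC-optimal
    threshold search, iterative-stratification cross-validation, and a
    synthetic testis-IHC image generator so the whole pipeline is testable
    without external image downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    jsonlite,
    png,
    tiff
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
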