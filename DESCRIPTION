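Package: mfinet
Title: Multi-Resolution Fusion Input Networks for Retinal Vessel Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patch-based segmentation of retinal blood vessels in fundus
    photographs with a multi-resolution fusion input (MR) encoder-decoder
    network using fully aggregated attention-gated skip connections (FAS).
    Provides fundus preprocessing (weighted channel fusion, normalization,
    CLAHE, gamma correction), 48x48 patch extraction and overlap-average
    reconstruction, a from-scratch CPU implementation of the network with
    reverse-mode automatic differentiation and Adam training, segmentation
    metrics (sensitivity, specificity, accuracy, precision, recall, F1,
    ROC/PR areas), paired significance tests for per-image F1, and a
    synthetic fundus generator with exact vessel and field-of-view ground
    truth so the whole pipeline is testable without dataset downloads.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
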