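Package: retseg
Title: Dense-Block U-Net Segmentation of Retinal Blood Vessels
Version: 0.1.0
Authors@R:
    person("retseg", "developers", email = "retseg@example.org",
           role = c("aut", "cre"))
Description: End-to-end toolkit for segmenting blood vessels in color fundus
    photographs. Implements the classical enhancement pipeline (green-channel
    extraction, contrast-limited adaptive histogram equalization, median
    filtering, min-max normalization, mean-anchored adaptive gamma correction
    and multi-scale morphological top-hat enhancement), random 48x48 patch
    amplification, a dense-block U-Net trained with stochastic gradient
    descent on a soft Dice loss with its analytic gradient, overlap-averaged
    whole-image reconstruction, and field-of-view restricted evaluation
    (accuracy, specificity, sensitivity, positive predictive value, ROC/AUC).
    Ships a synthetic fundus generator with known vessel ground truth so the
    whole pipeline is testable without access to clinical data, plus a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    zip,
    optparse,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
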