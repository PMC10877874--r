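Package: ovadx
Title: Edge-Output Segmentation and Multi-Indicator Diagnostics for Ovarian Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two complementary analyses of ovarian cancer data: a
    fully convolutional segmentation network for T2-weighted MRI slices built
    on a truncated residual backbone with three edge-output branches, trained
    with a class-balanced cross-entropy loss and evaluated with Dice,
    sensitivity, specificity and Hausdorff distance; and a multi-indicator
    diagnostic pipeline that z-scores a 25-indicator laboratory panel, reduces
    it to three principal components, classifies with a genetic-algorithm
    optimised back-propagation network and evaluates with ROC curves, the
    Youden operating point and the DeLong test for correlated AUCs. Synthetic
    phantom and cohort generators make every step testable without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    png,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    withr,
    RNifti
Config/testthat/edition: 3
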