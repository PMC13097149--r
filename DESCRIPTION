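Package: lesionnet
Title: Morphology-Guided, Explainable, Uncertainty-Aware Skin Lesion Classification
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale framework for dermoscopy-style skin lesion analysis
    combining U-Net lesion segmentation trained with Dice loss, background
    suppression by masking, a small convolutional classifier with channel and
    spatial attention regularized to align with lesion morphology, Grad-CAM and
    saliency explanation maps, and Monte Carlo dropout uncertainty with
    rejection analysis and calibration reporting. Includes a seeded synthetic
    dermoscopy-style image generator (class-conditional lesion morphology over
    a skin-like background with hair, illumination and noise artifacts),
    stratified cross-validation, per-class metrics with one-vs-rest ROC, an
    ablation-ready experiment runner and a command-line interface. All neural
    network components are implemented natively with Rcpp/RcppArmadillo
    compute kernels.
License: MIT + file LICENSE
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
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
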