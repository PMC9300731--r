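Package: fundusmtl
Title: Multi-Task Deep Learning for Glaucoma Screening from Color Fundus Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A compact multi-task convolutional framework for retinal fundus
    image analysis. One shared VGG-16 encoder-decoder network jointly learns
    optic-disc segmentation, optic-cup segmentation, fovea localization via
    Gaussian saliency-map regression, and glaucoma classification. Training
    supports three optimization strategies: a standard aggregated multi-task
    loss, plain alternating per-task gradient steps, and alternating steps
    with one independent optimizer state per task (MTL-IO), which prevents
    the moving averages of adaptive optimizers from mixing gradient history
    across tasks. Includes vertical cup-to-disc ratio (vCDR) scoring with a
    logistic classifier, ensemble glaucoma prediction, evaluation metrics
    (Dice, ROC AUC, fovea localization error), a seeded synthetic fundus
    generator with exact ground truth, REFUGE-style dataset input/output,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
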