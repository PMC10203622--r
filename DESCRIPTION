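Package: agcnet
Title: Attention-Guided Cascaded Network for Retinal Vessel Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-to-fine cascaded residual U-Net for pixel-level retinal
    vessel segmentation in fundus photographs. Two identical U-shaped
    backbones are cascaded through an inter-stage spatial attention module
    built from channel-pooled descriptors and parallel dilated convolutions,
    and trained with a pixel-importance-balance loss, a weighted cross-entropy
    whose per-pixel weight is a linear function of the vessel-pixel count in
    the surrounding 5x5 box, emphasizing thin vessels and vessel-adjacent
    background. Includes a deterministic synthetic fundus generator, DRIVE and
    CHASE_DB1 style data loaders with zero-pad and crop-back conventions,
    training with deep supervision and Adam, an ablation harness, and
    confusion-matrix, ROC and AUC evaluation. All forward and backward passes
    are implemented in R and C++; no external deep-learning framework is used.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    EBImage,
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
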