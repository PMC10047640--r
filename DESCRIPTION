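Package: osteoseg
Title: Edge-Enhanced Segmentation Toolkit for Osteosarcoma MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the computer-aided analysis of osteosarcoma MRI
    slices: a threshold screening filter (TSF) that discards redundant
    lesion-free slices, a fast non-local-means denoiser with FFT-based
    patch-distance computation and Rician bias correction for MR
    magnitude images, and TBNet, a skip-free U-Net segmentation network
    whose encoder scales are fused by a channel-wise cross-attention
    transformer and whose decoder uses edge-enhanced cross-attention,
    trained with a combined Dice and boundary (signed-distance) loss.
    A synthetic phantom generator with a Rician magnitude noise model
    makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    png,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
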