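Package: mtunet
Title: Dual-Encoder Mamba-Transformer U-Net for Polyp Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A hybrid encoder-decoder network for binary segmentation of
    colorectal polyps in endoscopy images. One encoder branch applies
    cross-shape (horizontal/vertical strip) multi-head self-attention, the
    other a bidirectional selective state-space (Mamba-style) sequence model;
    per-stage features are fused by a coordinate-attention merge module and
    decoded together with a depthwise-separable auxiliary stream. Includes a
    combined binary cross-entropy and Dice objective, segmentation metrics,
    a seeded synthetic polyp image generator, a small reverse-mode autodiff
    engine used for training on CPU, and parameter/FLOP profiling utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Matrix,
    Rcpp,
    png,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
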