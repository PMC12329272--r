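Package: unetbench
Title: U-Net Depth and Width Benchmarking for Chest Radiograph Lung Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Constructs and audits a family of eight U-Net encoder-decoder
    variants for binary lung-field segmentation of chest radiographs: four
    depth variants (7 to 13 convolutional stages with doubling filter
    schedules) and four width variants (a fixed 9-stage layout at 16 to 128
    filters per layer). Provides exact closed-form parameter accounting
    cross-checked against the built networks, the standard preprocessing
    chain (resize, Gaussian denoising, histogram equalization, mask
    binarization), pixelwise Jaccard (IoU) and Dice evaluation with micro and
    macro aggregation, a seeded synthetic chest-phantom generator with ground
    truth masks, and a reproducible train/evaluate harness (Adam, binary
    cross-entropy) with CSV reports and side-by-side mask panels. All network
    computation is implemented in the package with RcppArmadillo kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
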