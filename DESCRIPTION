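Package: synthmv
Title: Synthetic Megavoltage CBCT Generation for Pacemaker Visualization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for studying GAN-based translation of
    kilovoltage CT/CBCT images into synthetic megavoltage (MV) CBCT images in
    order to suppress metal streak artifacts around cardiac implantable
    devices and improve their contouring. Provides a seeded synthetic
    thorax-phantom generator with sinogram-domain streak simulation and
    filtered back-projection, rigid mutual-information registration,
    intensity clipping/normalization and body-masked patch extraction,
    compact conditional-GAN and cycleGAN trainers built on 2D convolutional
    kernels, and contour-agreement evaluation (Dice, surface Dice, HD95,
    mean surface distance) with rank-sum comparison of model routes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    RNifti,
    EBImage,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
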