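Package: epgnet
Title: Extra Proximal-Gradient Networks for Compressive-Sensing Image
    Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstruction of grayscale images from compressive
    measurements using an unrolled extra proximal-gradient network with
    learned soft-shrinkage regularization and an optional embedded-Gaussian
    nonlocal attention block. Provides the underlying accelerated extra
    proximal-gradient optimizer with pluggable proximal operators, sensing
    operators for block compressed sensing (row-orthonormalized Gaussian
    matrices) and compressed-sensing MRI (radial-mask partial Fourier),
    end-to-end network training with hand-derived reverse-mode gradients,
    a synthetic phantom generator for dataset-free experimentation, and
    PSNR/SSIM evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    png,
    tiff,
    yaml,
    jsonlite,
    optparse
Config/testthat/edition: 3
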