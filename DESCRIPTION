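Package: cbctshade
Title: Shading Correction of Narrow Field-of-View Cone-Beam CT with U-Net Transfer Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates truncated, scatter-corrupted cone-beam CT (CBCT) from
    CT-like volumes and restores CT-grade Hounsfield units with a convolutional
    U-Net trained by a two-stage transfer-learning protocol. Provides seeded
    digital pelvis phantoms, a fan-beam forward projector with a parametric
    scatter/beam-hardening/noise model, sinogram truncation handling by
    mirrored cosine extrapolation, short-scan filtered backprojection,
    slice-pair preprocessing, a from-scratch U-Net engine with symmetric
    deep-block fine-tuning, leave-one-out cross-validation over scan pairs,
    and an image-quality metric suite (PSNR, SSIM, MAE in HU, ROI and
    contrast-to-noise analyses).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    EBImage,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
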