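Package: fanrec
Title: Fan-Beam CT Reconstruction from Incomplete Sinograms with a
    Sinogram-Domain Residual U-Net
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for two-dimensional equi-spaced fan-beam computed
    tomography with incomplete projection data. Provides a seeded random
    ellipse phantom generator with exact (closed-form) fan-beam forward
    projection, a raster ray-driven projector, equi-spaced fan-beam
    filtered back-projection (FBP) with a band-limited ramp kernel,
    sparse-view and limited-angle degradation operators, and a residual
    U-net that restores complete sinograms from the corrupted sinograms
    obtained by re-projecting an initial FBP reconstruction. The network,
    including trainable strided-convolution down-sampling and max/mean
    pooling variants, batch normalization, Nadam optimisation and an
    exponentially decayed learning-rate schedule, is implemented natively
    with compiled convolution kernels, so the full train/infer loop runs
    without external deep-learning frameworks. PSNR-based evaluation
    reports and a command-line interface for dataset generation,
    training, inference and evaluation are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
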