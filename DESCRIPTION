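Package: sprmdeep
Title: Simulation, Deep Denoising and Single-Particle Analysis for
    Surface Plasmon Resonance Microscopy
Version: 0.1.0
Authors@R:
    person("SPRM", "Tools Contributors", email = "sprmdeep@example.org",
           role = c("aut", "cre"))
Description: A toolkit for surface plasmon resonance microscopy (SPRM)
    image sequences of single nanoparticles. Provides a physics-based
    forward simulator (parabolic interference point-spread functions,
    doubly stochastic Poisson shot noise), a spatio-temporal denoising
    network (residual U-Net feeding a bidirectional convolutional LSTM,
    implemented natively with analytic gradients), SNR-based sizing and
    calibration, Richardson-Lucy interferometric reconstruction,
    SSIM-based phase estimation, and 3D single-particle tracking with
    evanescent-decay axial localization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
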