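Package: sparus
Title: Sparse-Array Ultrasound Simulation, Beamforming and Learned
    Artifact Restoration
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying grating-lobe artifacts in sparse-aperture
    high-frequency ultrasound and their removal by a residual
    encoder-decoder network. Simulates plane-wave radio-frequency channel
    data from point-scatterer phantoms for a 128-element linear array and
    its 64- and 16-channel sparse decimations, reconstructs 8-bit B-mode
    frames by coherently compounded delay-and-sum beamforming with Hanning
    apodization, trains an RUNet-style restoration network on paired
    sparse/dense frames, and evaluates restoration with global SSIM, MSE,
    PSNR, FWHM, IoU, Bland-Altman agreement and t-test power analysis.
    Includes a synthetic phantom factory (wire, speckle, tooth/gingiva,
    negative controls) with automated gingival-thickness measurement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    rhdf5,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
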