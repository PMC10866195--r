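Package: prfst
Title: Spatiotemporal Population Receptive Field Modeling and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-computable forward models of spatiotemporal population
    receptive fields (pRFs) for visual fMRI: a conventional spatial 2D-Gaussian
    model, a compressive spatiotemporal (CST) model with sustained and on/off
    transient temporal channels, and a delayed-normalization spatiotemporal
    (DN-ST) model. Includes rendering of binarized traveling-bar stimulus
    sequences at 10 ms resolution, two-gamma hemodynamic response functions
    with voxel-wise optimization, a synthesizer that generates noisy simulated
    BOLD voxel time courses at a calibrated signal-to-noise ratio, a two-stage
    coarse-to-fine solver that recovers model parameters per voxel, and
    parameter-recovery evaluation (median absolute percentage error, model
    comparison by permutation testing, eccentricity binning).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
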