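Package: fcshydro
Title: Fluorescence Correlation Spectroscopy Fitting and Hydrodynamic Shape
    Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing fluorescence correlation spectroscopy (FCS)
    experiments on diffusing biomolecules: closed-form one- and two-species
    autocorrelation models for a 3D Gaussian observation volume (one- and
    two-photon excitation), weighted nonlinear least-squares fitting with
    model comparison and bootstrap uncertainties, beam calibration against a
    reference fluorophore, and conversion of diffusion coefficients to
    hydrodynamic size and shape via the Stokes-Einstein relation and the
    Perrin prolate-ellipsoid model under an equal-volume constraint. Includes
    a synthetic-data generator (noisy correlation curves, Brownian-dynamics
    photon traces with multi-tau correlation, pH-titration curve sets, toy
    trajectories) and molecular-dynamics post-processing statistics (mean
    square displacement and Einstein-relation diffusion, Kabsch-superposed
    RMSD, radius of gyration, Daura conformational clustering, C-alpha
    principal component analysis, free-energy landscapes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
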