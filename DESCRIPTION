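Package: metamove
Title: Two-Timescale Diffusion and Metastability Analysis of Animal Telemetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses GPS telemetry of territorial animals on two timescales.
    On the fast scale it estimates an isotropic diffusion constant per
    individual and month with a Kramers-Moyal finite-difference estimator and
    relates it to covariates through a log-link mixed-effects model. On the
    slow scale it approximates the Koopman operator of the movement process by
    extended dynamic mode decomposition (EDMD) over an indicator-function
    dictionary on a spatial box grid (equivalently, Ulam's method for a Markov
    state model), detects metastable home-range clusters from the dominant
    eigenfunctions, and summarises clusters and social-group home ranges as
    convex hulls. A stochastic-differential-equation movement simulator with a
    realistic GPS observation process provides ground-truthed synthetic data,
    and a cleaning pipeline (satellite/DOP quality filter, speed and jump
    filters, time snapping, monitoring-period splitting, linear interpolation
    to a uniform grid) prepares raw fix tables for both analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmmTMB,
    jsonlite,
    MASS,
    Matrix,
    Rcpp,
    stats,
    grDevices,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
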