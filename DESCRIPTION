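Package: hemodual
Title: Dual and Joint Unscented Kalman Filtering for the Balloon
    Hemodynamic Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for inverting the Balloon hemodynamic model from
    single-voxel BOLD (blood oxygenation level dependent) fMRI time
    series.  Implements the model dynamics with Runge-Kutta
    integration, the BOLD observation equation, a generic unscented
    Kalman filter (plain and noise-augmented sigma-point forms), and
    two complete nonlinear estimators: a dual filter that runs
    separate state and parameter filters alternately with no modelled
    state-parameter cross-covariance, and a baseline joint filter over
    the concatenated state.  Includes a seeded block-design BOLD
    simulator for recovery studies, a Cholesky-flops cost comparison
    of the two schemes, a model-fitting interface with the usual
    methods (coef, fitted, residuals, plot, simulate), and a small
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
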