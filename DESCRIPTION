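Package: dtwfc
Title: Dynamic Time Warping Functional Connectivity for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring resting-state fMRI functional connectivity
    with Dynamic Time Warping (DTW). Provides a Sakoe-Chiba banded DTW
    distance with warping-path backtracking, the standard baselines
    (zero-lag Pearson correlation and maximal-lag cross-correlation), a
    distance-to-similarity transform with surrogate-based empirical null
    calibration, the fMRI signal-conditioning chain (nuisance regression
    with optional global signal regression, DCT high-pass and bidirectional
    Butterworth low-pass filtering), seed-based connectivity maps and
    ROI-by-ROI connectivity matrices, fixed-effect group statistics with
    FDR control and preprocessing-sensitivity reports, a LASSO connectome
    classifier with nested leave-subject-out cross-validation, simulation
    experiments for transient interactions and common-noise robustness,
    and a synthetic 4D fMRI fixture generator.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    RNifti,
    MASS
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
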