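Package: drsifs
Title: Simulation and Classification Pipeline for Combined Diffuse
    Reflectance and Intrinsic Fluorescence Spectroscopy of Breast Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for six-channel diffuse reflectance (DRS) and intrinsic
    fluorescence (IFS) breast-tissue diagnostics: a physics-informed
    synthetic spectra generator (diffusion-dipole reflectance forward
    model, chromophore and fluorophore bases, instrument noise, the
    patient/sample/rotation-position acquisition hierarchy and sample
    quality grading), spectral preprocessing (integration-time and
    white-standard shape calibration, signal-to-noise gating,
    Savitzky-Golay smoothing, canonical spline resampling), fixed-window
    feature extraction, Boruta all-relevant feature selection, and
    patient-grouped repeated stratified cross-validated classification
    with gradient-boosted trees, reporting sensitivity, specificity,
    accuracy, AUC and mean average precision with confusion matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    ranger,
    signal,
    stats,
    tools,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
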