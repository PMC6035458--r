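Package: rsdmtox
Title: Rectum Surface Dose Maps and Toxicity Prediction for Combined
    EBRT and Brachytherapy
Version: 0.1.0
Authors@R:
    person("RSDM", "Maintainers", email = "rsdmtox@example.org",
           role = c("aut", "cre"))
Description: Toolkit for modelling the rectal dose-toxicity relationship in
    combined external beam radiotherapy (EBRT) and intracavitary
    brachytherapy (BT). Accumulates fractional rectal surface dose in
    equieffective 2 Gy fractions (EQD2) under the linear-quadratic model
    using non-rigid surface point registration, flattens the cumulative
    3D surface dose into a physical-length-preserving 2D rectum surface
    dose map (RSDM), extracts dose-volume parameters, gray-level texture
    features (GLCM, GLRLM, GLSZM, NGTDM) and dose-geometric parameters,
    and predicts binary rectal toxicity with a SMOTE-balanced support
    vector machine driven by sequential forward feature selection under
    repeated stratified cross-validation. Includes a fully deterministic
    synthetic-cohort generator so every pipeline stage is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
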