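Package: cufflessbp
Title: Cuffless Blood Pressure Estimation from ECG and PPG Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates systolic and diastolic blood pressure from synchronized
    electrocardiogram (ECG) and photoplethysmogram (PPG) waveform segments,
    using an arterial blood pressure (ABP) channel only as the reference and
    for subject-level personalization. Implements segment quality control,
    Pan-Tompkins R-peak and Elgendi PPG landmark detection, the 22 canonical
    time-series features plus hemodynamic, morphological and demographic
    features, three regression backends (elastic-net lasso, least-squares
    boosted trees, and a compact dense residual network), a test-time
    personalization and re-calibration protocol driven by mean-PPG drift, and
    the AAMI/BHS device-validation statistics (mean error, error standard
    deviation, mean absolute error, Bland-Altman limits, cohort composition
    checks, Levene and two-way ANOVA comparisons). A synthetic cohort
    generator produces ECG/PPG/ABP waveforms with known beat annotations,
    blood-pressure coupling and hemodynamic drift events, so the entire
    pipeline is testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    glmnet,
    xgboost,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    rhdf5,
    car,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
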