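Package: sparkspec
Title: Tissue Classification from Electrosurgical Spark Emission Spectra
Version: 0.1.0
Authors@R:
    person("sparkspec", "developers", email = "sparkspec@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for optical emission spectroscopy (OES) of
    electrosurgical sparks on tissue: spectrum and cohort input/output with
    acquisition-level quality control, local-baseline signal-to-noise
    estimation with a carbon-line quality gate, emission-line peak detection
    and catalogue matching, feature-panel selection by occurrence rate,
    total-intensity normalization and windowed feature integration,
    leave-one-patient-out support-vector classification with per-patient
    diagnostic metrics (accuracy, sensitivity, specificity, PPV, NPV), and a
    synthetic spark-spectrum cohort generator for end-to-end testing without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
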