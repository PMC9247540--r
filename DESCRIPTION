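Package: fluidroc
Title: Diagnostic Evaluation of Fluid-Responsiveness Predictors Around a
    Lung Recruitment Maneuver
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate hemodynamic predictors of fluid
    responsiveness measured around a lung recruitment maneuver (LRM) and a
    volume-expansion (VE) challenge: relative-change statistics and
    responder classification, empirical ROC curves with DeLong confidence
    intervals and paired AUC comparison, Youden-index cutoff selection,
    exact (Clopper-Pearson) and log-method confidence intervals for
    diagnostic metrics, the two-approach gray-zone (inconclusive interval)
    procedure, four-quadrant trending concordance, and Obuchowski's ROC
    sample-size method. Includes a calibrated synthetic-cohort generator
    so the full pipeline is testable without patient-level data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
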