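Package: vitalwatch
Title: Deterioration Detection from Continuous Vital Signs in Critical
    Congenital Heart Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Continuous classification of per-second multiparameter
    vital-sign streams (heart rate, respiratory rate, SpO2, bilateral
    cerebral rSO2, invasive mean blood pressure, EtCO2) from perioperative
    neonates with critical congenital heart disease into stable, unstable
    and sensor-dysfunction states. Combines rule-based sensor-artifact
    detection, a population-level one-class support vector machine over
    Mahalanobis-prefiltered parameter vectors, and patient-specific
    baseline-deviation analysis with streaming medians, followed by
    moving-window episode aggregation. Includes a stratified synthetic
    vital-sign simulator with ground-truth labels and an evaluation
    harness reporting episodic and time-percentual performance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
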