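Package: htnrec
Title: Causal Ensemble Modelling of First-Line Antihypertensive Treatment Success
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for individualized first-line hypertension management from
    longitudinal electronic-health-record style tables: a synthetic cohort
    generator with a planted treatment-response surface, cohort construction
    with guideline-era inclusion and exclusion criteria, medication
    normalization to ingredient and daily-dose resolution, rule-based
    treatment-success labelling (JNC 8 blood-pressure goals plus adverse-effect
    criteria), a deep-ensemble success model with percentile uncertainty bands
    and a positivity-aware confidence tier, a JNC 8 first-line guideline
    engine, and the associated evaluation metrics (precision/recall/F1,
    confidence-stratified metrics, class success tables, guideline agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    nnet,
    stats,
    utils,
    withr,
    generics,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
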