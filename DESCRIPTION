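Package: ctrtest
Title: Chemoresistance Assay Scoring and Clinical Response Evaluation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for in vitro chemotherapy resistance testing
    of tumor samples. Computes percent cell growth inhibition (PCI) from
    scintillation counts of treated wells and lethal-dose/no-drug controls,
    classifies drugs into extreme, medium and slight resistance (ER/MR/SR)
    against per-drug reference populations, scores two-drug combinations on
    the additive 0-4 scale, and evaluates agreement between predicted
    resistance class and clinical response: per-class responder proportions
    with exact Clopper-Pearson intervals, ties-corrected ordinal ROC/AUC and
    DeLong confidence intervals. Bundles a 52-patient ovarian-cancer cohort
    and historical contingency tables as plain-text fixtures, and includes a
    seeded synthetic-data generator for end-to-end testing and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
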