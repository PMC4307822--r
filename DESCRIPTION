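Package: vrdot
Title: Scoring and Screening Analysis for Virtual-Reality Day-Out Task
    Assessments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores session event logs from a virtual-reality fire-evacuation
    day-out task with an efficacy-ratio-based functional impairment index,
    calibrates the four error-penalty weights of the index against cognitive
    and functional scales, derives psychomotor metrics (gait speed, stride
    length, tapping rate) with knee-heel normalisation, estimates annual
    rates of change from yearly visits, and runs a screening battery:
    Spearman and partial Spearman correlations, ROC curves with bootstrap
    confidence intervals and Youden cutoffs, and logistic models of
    conversion from amnestic mild cognitive impairment to Alzheimer-type
    dementia. A synthetic three-group cohort generator with group-anchored
    distributions makes every stage of the pipeline testable without
    clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
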