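Package: bleedpheno
Title: Bleeding Phenotyping and Antithrombotic Safety Analyses for Linked
    Electronic Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rule-based phenotyping of bleeding events from linked
    primary-care, hospital-admission and death-registry electronic health
    records, including fatal-bleeding detection, four markers of bleeding
    severity, inference of uncoded bleeds from transfusion, anaemia,
    haemoglobin and endoscopy records, and three prognostic severity
    classes. Also provides prescription-episode construction for a
    seven-state antithrombotic exposure model, cohort assembly with
    baseline covariates, a synthetic linked-EHR generator with known
    ground truth, and a survival-analysis layer (Kaplan-Meier incidence,
    monthly event rates with loess trends, counting-process construction
    and time-dependent Cox models, recurrent-bleeding curves, and
    diagnostic-accuracy metrics with exact confidence intervals).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14.0),
    survival,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
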