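Package: btcbm
Title: Multi-Omics Biomarker Analysis for Single-Arm Immuno-Chemotherapy Trials in Biliary Tract Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploratory biomarker analysis of single-arm
    immuno-chemotherapy trials in biliary tract cancer. Implements a
    binomial per-locus microsatellite-instability (MSI) caller with a
    baseline-panel prior, tumor mutational burden and pathway-level
    mutation biomarkers from MAF-like call tables, housekeeping-normalized
    immune metagene and signature scoring for panel expression counts,
    Kaplan-Meier / log-rank / Cox survival stratification, exact 2x2
    association testing with Clopper-Pearson response-rate intervals, the
    exponential single-arm trial design calculation, and a seeded
    synthetic-cohort generator that emulates the trial's statistical
    structure for testing and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
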