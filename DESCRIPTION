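Package: widqec
Title: Cervicovaginal DNA Methylation Triage for Endometrial Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Development and evaluation pipeline for a three-marker
    MethyLight (methylation-specific qPCR) triage test for endometrial
    cancer in cervicovaginal specimens. Simulates array-scale methylation
    screens with epithelial/immune cell-mixture structure and matching qPCR
    plates; discovers marker regions with an immune-contamination-aware
    per-CpG screen and proximity clustering; computes
    percentage-of-methylated-reference (PMR) values and the summed
    three-reaction score; fixes dual high-sensitivity/high-specificity
    decision thresholds; and evaluates diagnostic performance with exact
    binomial confidence intervals, predictive values under assumed
    prevalence, empirical ROC curves, DeLong paired AUC comparison, exact
    McNemar tests, and covariate- and time-to-diagnosis-stratified
    summaries.
License: MIT + file LICENSE
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
    withr,
    pROC
Config/testthat/edition: 3
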