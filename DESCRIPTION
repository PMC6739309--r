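Package: riskscan
Title: Biomarker Cut-Point Discovery and Risk Stratification for Clinical Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exhaustive threshold scanning for prognostic biomarkers with
    per-cut-off 2x2 confusion matrices, Fisher exact and chi-square tests and
    risk-ratio ledgers; Kaplan-Meier and log-rank comparison of the
    dichotomized groups; genetic-algorithm subset selection of binomial GLMs
    ranked by BIC to find biomarker interactors; gene-signature overlap
    summaries; and a seeded synthetic sepsis-cohort generator with
    copula-linked covariates so every stage runs without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
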