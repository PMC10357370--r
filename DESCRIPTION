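Package: hrbindex
Title: Health Risk Behavior Scoring and Anxiety-Depression Comorbidity
    Analysis for Adolescent Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores the questionnaire instruments used in adolescent
    health-risk-behavior (HRB) surveys (GAD-7, PHQ-9, PAR-3, a four-item
    diet composite, last-month smoking days, and MCTQ-derived sleep
    duration), combines the four behavior risk levels into a weighted HRB
    risk index, classifies anxiety-depression comorbidity, and analyses
    the association between the two with contingency-table chi-square
    tests, Woolf odds-ratio confidence intervals, Spearman correlations,
    and binary logistic regression fitted by iteratively reweighted least
    squares.  Ships a synthetic survey-cohort generator with exact
    frequency-table expansion and known-truth logistic outcome models for
    parameter-recovery validation, plus an end-to-end pipeline from raw
    survey CSVs to report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
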