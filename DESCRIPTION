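Package: pesval
Title: Scoring and Validation of the Pattern Element Scale for Dementia
    Subtyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scoring engine and full validation toolkit for the Pattern
    Element Scale (PES), an 11-subscale weighted-checklist instrument for
    traditional-medicine subtyping of dementia. Computes subscale scores and
    pattern-element diagnoses from item responses; evaluates diagnostic
    accuracy against an expert standard (sensitivity, specificity, predictive
    values, Cohen's kappa, Pearson chi-square, ROC curves with nonparametric
    AUC standard errors); reconstructs per-subscale 2x2 confusion tables from
    published summary percentages by exhaustive integer enumeration; performs
    canonical correlation analysis between subscale scores and MMSE cognition
    domains (Wilks' lambda, Bartlett chi-square tests, cross loadings); and
    simulates synthetic dementia cohorts with latent pattern-element status,
    rater error and expert adjudication for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
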