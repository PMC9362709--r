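Package: cati
Title: Construction and Validation of Hedonically Weighted Child Well-Being Indices
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds composite child and adolescent well-being indices from binary
    outcome indicators using a hedonic "double weighting" scheme: candidate
    components are screened against multiple subjective well-being scales with an
    adaptive LASSO under multiple imputation, surviving coefficients are combined
    with first-principal-component loadings of the scales into normalized index
    weights, and individuals are scored as a weighted sum of their positive
    indicators. Includes chained-equations multiple imputation with Rubin pooling,
    predictive-validity models (average marginal effects, partial R-squared,
    robust Poisson earnings models, seemingly-unrelated index comparisons), a
    synthetic cohort generator with known ground truth for end-to-end testing,
    and a golden check against the published CATI 1.0 weights.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    sandwich,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
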