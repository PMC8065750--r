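Package: aspos
Title: Scoring and Psychometric Validation of the Adam's Scale of Posterior Stroke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Adam's Scale of Posterior Stroke (ASPOS), a
    seven-item ordinal instrument (total 0-19) for grading posterior
    circulation stroke severity, together with the full clinimetric
    validation toolkit used to evaluate such instruments: Cronbach's alpha
    with item-rest correlations and alpha-if-item-deleted, two-way
    intraclass correlation coefficients, weighted Cohen's kappa,
    Bland-Altman repeatability analysis, Spearman construct and predictive
    validity, Kruskal-Wallis and Mann-Whitney group comparisons, and a
    zero-cell-safe odds ratio for severity-threshold analysis. A synthetic
    cohort generator built on a latent-trait threshold model reproduces the
    design of a multi-rater validation study (three raters plus a retest,
    companion stroke scales at day 1 and day 90) so the entire pipeline can
    be exercised and tested without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
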