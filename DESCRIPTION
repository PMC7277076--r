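Package: cigdc
Title: Validation Toolkit for Ordinal Screening Scales with a Second-Order
    Factor Structure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to validate multidimensional ordinal screening
    instruments against a binary diagnostic reference, built around the
    27-item Chinese Internet Gaming Disorder Checklist (C-IGDC).
    Simulates 3-point Likert item responses from a second-order
    confirmatory factor model, estimates polychoric correlations by
    two-stage maximum likelihood, fits second-order and one-factor
    measurement models by (diagonally weighted) least squares with the
    usual fit indices (CFI, TLI, RMSEA, SRMR), reduces the item pool by
    the top-loadings rule, computes reliability (Cronbach's alpha,
    KR-20) and criterion validity statistics, and selects an optimal
    screening cutoff from ROC/2x2 efficacy indices (sensitivity,
    specificity, predictive rates, Cohen's kappa, Youden's J,
    diagnostic odds ratio) with a multi-index tie-break rule.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
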