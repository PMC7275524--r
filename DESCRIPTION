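Package: compbdt
Title: Comparison of Two Binary Diagnostic Tests Under a Paired Design
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimation and simultaneous comparison of the performance of two
    binary diagnostic tests applied to the same subjects, with disease status
    resolved by a gold standard (paired design). Provides point estimates and
    standard errors for prevalence, sensitivity, specificity, likelihood
    ratios and predictive values; modified-Wilson and approximate-score
    confidence intervals with good small-sample coverage; global Wald and
    likelihood-ratio tests for each parameter family with Holm step-down
    resolution of the individual hypotheses; oriented confidence intervals for
    significant contrasts; and Monte Carlo estimation of the power or of the
    probability of a type II error by multinomial resampling of the observed
    table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
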