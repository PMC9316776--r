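Package: mlcount
Title: Multilevel Count Regression Models for Zero-Inflated Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits two-level count regression models to hierarchical survey
    data in which mothers (or other units) are nested within regions and the
    outcome is an overdispersed, zero-heavy event count. Six model families
    are supported (Poisson, negative binomial, zero-inflated Poisson,
    zero-inflated negative binomial, hurdle Poisson, hurdle negative
    binomial), each with normally distributed region-level random intercepts
    and slopes integrated out of the likelihood by adaptive Gauss-Hermite
    quadrature (one random term) or a Laplace approximation (several).
    Includes descriptive diagnostics for overdispersion and excess zeros,
    deviance/AIC/BIC model comparison, rate-ratio effect reporting, a
    generator for synthetic two-level survey-like datasets with known truth,
    and an end-to-end describe/fit/compare pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    glmmTMB
Config/testthat/edition: 3
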