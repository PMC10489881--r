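Package: trampler
Title: Trampling-Disturbance Analysis for Alpine Plant Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for analysing the effects of trail-side
    trampling disturbance on alpine plant communities surveyed with paired
    disturbed/undisturbed transects along elevational gradients. Provides
    green-pixel percent-cover estimation from quadrat photographs
    (saturation standardisation followed by green-channel-dominance
    classification), derivation of growth and area-standardised
    reproduction traits from per-plant field records, hierarchical Bayesian
    generalized linear mixed models (negative binomial and Beta families
    with a transect-pair random intercept) fitted with a built-in adaptive
    Metropolis-within-Gibbs sampler, and a model-checking suite (split
    R-hat, bulk/tail effective sample size, skewness posterior predictive
    checks, Pareto-smoothed importance-sampling leave-one-out
    cross-validation). A synthetic-survey generator with known ground truth
    makes every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jpeg,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
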