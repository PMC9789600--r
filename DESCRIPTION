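Package: dmftrend
Title: Age-Spatio-Temporal Small-Area Estimation of Deciduous Caries Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Small-area estimation of national and sub-national trends in
    deciduous-teeth caries indices (dmft and its decayed, missing and filled
    components) from sparse survey data.  A first-stage random-intercept
    mixed-effects model with covariate-driven fixed effects and crossed
    province and year intercepts is combined with age-spatio-temporal kernel
    smoothing of its residuals (binary province-adjacency spatial weights,
    tricube-type temporal weights, exponential age-distance weights),
    parametric multilevel-bootstrap uncertainty intervals, and direct
    age-standardisation against census population weights.  Includes a
    synthetic-data generator that emulates the sparse multi-survey design so
    that every stage of the pipeline can be validated by parameter-recovery
    and interval-coverage experiments without access to survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
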