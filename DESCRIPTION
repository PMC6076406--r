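Package: nutledger
Title: National Nutrient Availability Accounting and Panel Completion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for building national nutrient-availability panels from
    food supply and composition data: refuse-adjusted food-to-nutrient
    accounting, Atwater energy conversion and carbohydrate-by-difference,
    three-stage spatiotemporal Gaussian-process smoothing of sparse
    country-year panels with uncertainty draws, Socio-demographic Index
    construction with development quintiles, macronutrient substitution
    analysis, and prediction of dietary intake from national availability.
    Includes a synthetic-world generator with known ground truth so the
    full pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    lme4
Suggests:
    testthat (>= 3.0.0),
    ranger,
    xgboost,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
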