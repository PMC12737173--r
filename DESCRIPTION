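Package: aridsuit
Title: Ensemble Habitat Suitability Modelling and Aridity-Driven Change
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for climate-suitability analysis of
    crop species: spatial rarefaction of occurrence records and
    pseudo-absence generation, multicollinearity screening by iterative
    variance-inflation-factor pruning, multi-algorithm ensemble species
    distribution modelling gated by AUC and True Skill Statistic
    thresholds, equal-interval suitability classification with km2 area
    accounting, gain/loss/stable change mapping between reference and
    future periods, Thornthwaite potential evapotranspiration and the
    UNEP Aridity Index, and binomial logistic attribution of projected
    habitat loss to aridity. Ships a synthetic-world generator with a
    known ground-truth suitability surface so the whole pipeline is
    testable against parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    xgboost,
    e1071,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    geosphere
Config/testthat/edition: 3
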