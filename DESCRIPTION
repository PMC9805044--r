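Package: sdmuq
Title: Uncertainty Partitioning for Climate Projections of Species
    Distributions
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation framework for quantifying and partitioning
    uncertainty in long-term climate projections of marine species
    distributions. Generates divergent synthetic earth-system-model
    (ESM) forcing for a California Current-like domain, simulates
    "true" presence and biomass for three species archetypes (highly
    migratory, coastal pelagic, groundfish) from habitat-suitability
    operating models, fits an ensemble of hurdle (delta)
    species-distribution models (GAM, GLMM-surrogate, boosted trees,
    neural network) under multiple covariate parameterizations,
    measures projection skill decay and multivariate environmental
    novelty (ExDet NT1/NT2), and partitions ensemble prediction
    variance among ESM forcing, model type, and parameterization by
    dominance analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    mgcv,
    nnet,
    xgboost,
    data.table,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    pROC
Config/testthat/edition: 3
biocViews: Software, StatisticalMethod, Regression
RoxygenNote: 7.3.3
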