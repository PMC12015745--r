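Package: yartsa
Title: Ensemble Species Distribution Modelling for Ophiocordyceps sinensis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable, tested implementation of an ensemble species
    distribution modelling (SDM) workflow for the caterpillar fungus
    Ophiocordyceps sinensis (yartsa gunbu) on the Tibetan Plateau: occurrence
    cleaning, pseudo-absence sampling, a two-tier variable-selection workflow,
    a multi-algorithm single-model suite evaluated by AUC and the true skill
    statistic (TSS), TSS-gated ensemble combination (mean, median, committee
    averaging, TSS-weighted mean), ROC-threshold binarization, future-scenario
    projection with GCM consensus under no dispersal, Getis-Ord Gi* hotspot
    detection, habitat-centroid migration tracking, and area-proportional
    production economics. A synthetic-world generator supplies spatially
    autocorrelated environmental rasters with a known truth suitability so the
    whole pipeline is exercisable and testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    glmnet,
    rpart,
    randomForest,
    xgboost,
    mgcv,
    nnet,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'economics.R'
    'occurrences.R'
    'evaluation.R'
    'grid.R'
    'learners.R'
    'ensemble.R'
    'futures.R'
    'pipeline.R'
    'spatial_stats.R'
    'synthetic_world.R'
    'variable_screen.R'
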