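Package: seedmenus
Title: Ensemble Species Distribution Models and Seed-Menu Decision Support
    for Desert Restoration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An ensemble species-distribution-modelling (SDM) pipeline for
    presence-only occurrence data, and a spatial decision-support engine
    that turns stacked habitat predictions into site-specific "seed menus"
    of native plant species for restoration planning.  Three algorithm
    families (penalized additive models, random forests, and a
    maximum-entropy presence/background learner) are fit over a
    combinatorial model space constrained by covariate correlations,
    evaluated by cross-validation (AUC, True Skill Statistic, continuous
    Boyce index, AICc), and combined into TSS-weighted ensembles with
    standard-error layers, relative variable importance, and model-averaged
    response curves.  The menu engine stacks per-species habitat rasters,
    extracts probabilities at restoration sites (points or polygons),
    applies suitability thresholds (fixed or maximum sensitivity plus
    specificity), and joins species trait attributes.  A systematic-bias
    diagnostic regresses aggregated habitat probabilities on distance to
    development.  A synthetic-data generator (autocorrelated landscapes,
    logistic virtual species, access-biased occurrence sampling, trait
    tables) provides ground truth for validation, and a published
    49-species performance table is bundled as a results fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    mgcv,
    randomForest,
    glmnet,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
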