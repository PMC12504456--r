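Package: coinvade
Title: Predicting Occurrence and Co-Invasion of Two Invasive Plant Genera
    from Fused Field and Remote-Sensing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for presence-absence habitat suitability
    modelling of two co-occurring invasive Asteraceae genera (Erigeron spp.
    and Solidago spp.) in heterogeneous post-industrial landscapes. Derives
    plot-level field predictors (species counts, convex-hull Functional
    Richness, community-weighted mean traits, an NMDS succession axis) and
    multi-resolution remote-sensing predictors (canopy-height focal
    statistics, multi-temporal NDVI/LST compositing, spectral bands,
    moving-window Rao's Q spectral diversity); trains and tunes gradient
    boosting, radial-kernel support vector machine and random forest
    classifiers under repeated stratified cross-validation with AUC-based
    tuning; links field and remote-sensing predictors by redundancy analysis
    with VIF screening; and produces pixel-based probability maps,
    sensitivity-specificity balanced binary masks, a co-invasion
    intersection layer, land-cover coverage accounting and group contrasts.
    A synthetic landscape generator with known niche structure makes the
    whole workflow testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    vegan,
    randomForest,
    kernlab,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
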