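Package: islesdm
Title: Ensemble-of-Small-Models Workflows for Island Species Distributions
    and Diversity Hotspots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for climate-change impact assessment of island faunas with
    sparse occurrence data. Provides a synthetic-archipelago generator with
    virtual species of known niches, derivation of bioclimatic, potential
    evapotranspiration and topographic predictor stacks from monthly climate
    grids, collinearity filtering (Spearman and VIF), occurrence cleaning with
    spatial thinning and an accessibility sampling-bias model, per-species
    Ensembles of Small Models (bivariate Random-Forest classifiers weighted by
    the True Skill Statistic under spatial-block cross-validation), projection
    diagnostics (clamping, maxSSS binarization, ExDet extrapolation metrics,
    niche-truncation index, range-size change under dispersal constraints),
    species-richness and corrected-weighted-endemism hotspot mapping with
    altitudinal and circular shift tests, and protected-area overlap analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    mgcv,
    igraph,
    geosphere,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
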