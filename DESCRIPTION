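Package: macrosdm
Title: Bias-Weighted Boosted Regression Tree Ensembles for Species
    Distribution Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Presence-only species distribution modelling with boosted
    regression trees, built around survey-effort-weighted pseudo-absence
    sampling. Provides a lightweight geographic raster data model with
    plain-text grid I/O and latitude-aware cell areas, occurrence thinning
    to grid resolution, replicate pseudo-absence ensembles of boosted
    regression trees with cross-validated selection of the number of
    trees, relative-influence summaries, projection onto future climate
    scenarios, and accounting of change in highly suitable area in square
    kilometres. A virtual-species simulator generates covariate stacks,
    sampling-bias surfaces and occurrence records with known ground truth
    so the whole pipeline can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    geosphere,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
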