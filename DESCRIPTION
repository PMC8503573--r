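Package: HabitatQuality
Title: Boosted Regression Tree Habitat Suitability and Medicinal Quality Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An ensemble presence-background species distribution workflow for
    medicinal plants, built around from-scratch boosted regression trees
    (Bernoulli deviance, bagged, cross-validated tree selection) with
    relative-influence and partial-dependence summaries. Background points are
    screened by climate and elevation rules, resampled across ensemble
    iterations, and aggregated into mean and standard-deviation suitability
    rasters. Compound contents are linked to the main ecological factors by
    stepwise multiple linear regression; the fitted (or published) equations
    are applied as raster layers, overlaid on suitability, and classified by
    exact Fisher-Jenks natural breaks into a four-level high-quality growing
    area map. A synthetic-data module generates environment stacks, a known
    true-suitability surface, occurrence records and compound tables so every
    stage is testable without external downloads. Rasters use the ESRI ASCII
    grid format throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, xgboost, pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
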