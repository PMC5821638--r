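Package: agbUpscale
Title: Monte-Carlo Two-Stage Upscaling of Forest Aboveground Biomass
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping forest aboveground biomass (AGB) from plot
    networks, airborne LiDAR strips and wall-to-wall satellite imagery with
    per-pixel uncertainty. Implements a field-error budget (measurement,
    allometry and sampling components combined in quadrature), Monte-Carlo
    propagation of the field error through rule-based model-tree regression
    (an M5-style learner with multivariate linear leaf models and smoothed
    predictions), one- and two-stage upscaling scenarios with reference-pixel
    screening, per-pixel CI95 and relative-uncertainty surfaces, multi-temporal
    SAR speckle filtering with equivalent-number-of-looks diagnostics, and
    stratified calibration/validation with pixel-, hexagon- and region-level
    forest-area-weighted statistics. A synthetic-scene generator emulating the
    joint structure of inventory plots, LiDAR strips and SAR/optical predictor
    layers makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), rpart, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'errorBudget.R'
    'modelTree.R'
    'mcUpscaling.R'
    'sarTools.R'
    'utils.R'
    'syntheticScene.R'
    'validation.R'
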