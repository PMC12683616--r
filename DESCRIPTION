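Package: lightgap
Title: Lightning Disturbance in an Individual-Based Forest Gap Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A spatially explicit, individual-based forest dynamics simulator
    on a 1 m voxel grid with a three-stage tree mortality scheme: background
    mortality and carbon starvation, treefall with secondary damage, and
    lightning strikes. Lightning mortality follows a two-parameter
    community-level risk model (direct-hit probability and a distance/size
    decay exponent) and a species-specific generalization that shifts the
    log-odds of death by a per-species lightning tolerance. Includes
    grid-search calibration of the community-level model against binned
    field mortality counts, Sobol'-sequence parameter-uncertainty ensembles,
    lightning-frequency sweeps with tolerance-binned biomass summaries, and
    synthetic generators for species traits, meteorological forcing, and
    binned mortality observations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
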