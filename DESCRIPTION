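Package: fuzzsdm
Title: Hybrid Presence-Only to Presence-Absence Species Distribution
    Modelling with a Fuzzy Conservation Overlay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models species distributions from presence-only bottom-trawl
    records by chaining Ecological Niche Factor Analysis (ENFA) habitat
    suitability, environmentally- and geographically-weighted pseudo-absence
    generation, and logistic regression-kriging on Hill-Smith ordination
    components, with stepwise AIC selection and 10-fold cross-validated
    accuracy metrics (AUC, point-biserial correlation, sensitivity,
    specificity). Probability maps are converted to fuzzy membership
    surfaces via an ensemble of four threshold-optimisation criteria and
    combined across species with the fuzzy AND operator to map
    conservation-priority areas. Includes a seeded synthetic seascape and
    virtual-species generator with imperfect detection so the whole
    pipeline is testable end to end, plus ESRI ASCII raster input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
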