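Package: coastniche
Title: Coastal Niche Modelling with Scenario Attribution and Global
    Sensitivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Presence-only maximum-entropy niche modelling for coastal
    species, with AICc tuning over regularization and feature-class
    grids, extended-FAST variance-based global sensitivity analysis of
    predictor importance and interactions, scenario projection under
    climate change and sea-level rise, and a Venn four-set decomposition
    attributing habitat gain and loss to pure, shared, and coupling
    effects. Includes a synthetic coastal-landscape generator so the
    full workflow runs without external GIS data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
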