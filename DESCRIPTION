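Package: metstab
Title: Stability Analysis for Multi-Environment Crop Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Yield-stability analysis for multi-environment trials of the kind
    used in maize hybrid evaluation under sole cropping and intercropping:
    combined analysis of variance with a season x cropping-system x genotype
    partition, AMMI (additive main effects and multiplicative interaction)
    decomposition with the AMMI Stability Value, GGE biplot analysis including
    discriminativeness-vs-representativeness, mean-vs-stability and
    which-won-where mega-environment views, rank-based Genotype Stability
    Index, and Land Equivalent Ratio for intercropping. Includes a synthetic
    trial-data generator with known additive and low-rank multiplicative
    structure so every stage of the pipeline can be verified against planted
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
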