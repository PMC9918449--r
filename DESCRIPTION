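Package: barleywl
Title: Barley Waterlogging Stress Simulation and Seasonal Stress Typologies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale barley growth simulator with process-based
    waterlogging stress physiology: photosynthesis and phenology stress
    indices driven by the fraction of roots in saturated soil, stage-dependent
    phenology modifiers, and a three-stage response/adaptation model for
    genotypic waterlogging tolerance. Includes a seeded stochastic weather
    generator (Markov-chain rainfall occurrence with gamma amounts), monthly
    delta-change climate scenarios with an SSP585 CO2 trajectory, a layered
    bucket soil water balance, k-means clustering of seasonal stress
    trajectories into recurrent waterlogging typologies, and a genotype x
    environment x management factorial pipeline computing yield-loss and
    yield-penalty metrics, stress-pattern frequency shifts and
    waterlogging-tolerance benefits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
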