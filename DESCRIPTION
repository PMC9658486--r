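Package: acaciabm
Title: Volume-Based Allometric Biomass and Nutrient Models for Shrub-Like Acacia Stands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and applying volume-based allometric biomass
    models for shrub-like woody invaders such as Acacia longifolia. Computes
    canopy geometry (conic plant volume, canopy area) from field measurements
    and from photogrammetric canopy height grids (surface volume, vegetation
    cover area, mean height); fits a zoo of linear, log-linear and shifted
    power-law models over enumerated predictor sets with BIC-based selection
    of best and most-parsimonious equations; estimates biomass partitioning
    breakpoints by continuous two-segment (hinge) regression with Davies'
    test for a change in slope; runs the Monte-Carlo height-subsampling
    procedure that determines the minimum number of height observations per
    area needed for biomass prediction; and extrapolates carbon, nitrogen and
    phosphorus pools from tissue chemistry. A synthetic-data generator
    emulating destructive-harvest and UAV-photogrammetry campaigns makes the
    whole pipeline testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
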