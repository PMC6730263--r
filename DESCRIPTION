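Package: grassflux
Title: Chamber Fluxes, Isotope-Based Evapotranspiration Partitioning and
    Seasonal Carbon-Water Budgets for Grassland Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processes open dynamic chamber gas-exchange measurements into
    net ecosystem exchange (NEE) and evapotranspiration (ET), partitions NEE
    into gross primary production and ecosystem respiration via dark-chamber
    readings, partitions ET into soil evaporation and plant transpiration
    from oxygen-18 signatures (flux mass balance, Craig-Gordon evaporation
    model, isotopic steady state), integrates campaign days to daily sums
    with loess smoothing and night extrapolation rules, and fuses chamber
    daily sums with a continuous eddy-covariance series through
    correlation-gated additive offsets to derive stage and growing-season
    carbon and water budgets and water use efficiencies. Includes a
    synthetic grassland-season generator with known ground truth (four
    treatments crossing nitrogen addition and rain-out shelters) so every
    stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
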