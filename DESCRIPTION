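Package: tryforge
Title: Test Reference Years for Dynamic Climate Simulation in Controlled
    Environment Facilities
Version: 0.1.0
Authors@R:
    person("TRY", "Forge Developers", email = "tryforge@example.org",
           role = c("aut", "cre"))
Description: Generates hourly, multivariate Test Reference Years (TRYs) for
    forcing climate chambers in ecotron-class controlled environment
    facilities.  Computes additive delta-change climate signals from regional
    climate model ensembles (with specific-humidity to relative-humidity
    conversion and low-order Fourier smoothing of daily climatologies),
    resamples homogeneous multi-day weather segments from a multi-decade
    hourly station record by rank scoring against scenario reference
    climatologies, rescales ozone and carbon dioxide to scenario targets,
    adapts the resulting annual cycles to facility constraints (temperature
    and humidity clipping, global radiation to PPFD conversion and
    compression, ozone treatment gradients, slew-rate limited minute ramps),
    and evaluates them with climate extreme indices, kernel density
    estimates, and prescribed-versus-measured deviation statistics.  A
    seeded synthetic fixture generator provides a station record, a CO2
    record, a mock model ensemble with injected climate signals, and noisy
    facility logs so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
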