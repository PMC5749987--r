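Package: minexpam
Title: Passive Acoustic Monitoring Analysis of Dolphin Responses to Underwater Detonations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing duty-cycled passive acoustic monitoring data
    collected around naval mine-neutralization training: detection and size
    classification of underwater-detonation (UNDET) transients from hydrophone
    recordings, an ordinal dolphin acoustic-activity index with hourly
    aggregation, event-relative comparison windows at hour and day scales,
    paired response statistics with effect sizes, beta-regression generalized
    additive modelling of normalized hourly activity with all-subsets AICc
    selection, and a semi-empirical similitude model for sound exposure level
    and peak pressure of shallow-water detonations. A synthetic acoustic-scene
    simulator generates recording schedules, signal-count time series with
    diel, seasonal and response structure, and rendered waveforms so that the
    full pipeline can be exercised and validated without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    mgcv,
    stats,
    utils,
    yaml,
    zoo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
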