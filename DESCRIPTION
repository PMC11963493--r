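Package: drydownr
Title: Analysis of Soil-Plant-Atmosphere Drydown and Rewatering Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for processing and analysing intensive drydown-rewatering
    experiments on potted trees: heat-pulse sap flow cleaning
    (negative-excursion removal, Hampel filtering, baseline correction),
    vapour pressure deficit computation, bimodal van Genuchten water
    retention fitting and inversion, stable water isotope arithmetic and a
    dual-isotope mixing inversion for mean water-uptake depth, daily
    summarisation of sensor and sampling-day measurements, and
    period-stratified mutual information analysis of variable dependence.
    A synthetic experiment generator with known ground truth (layered soil
    bucket model, stem capacitor, stress-legacy stomatal memory, isotope
    tracers) supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
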