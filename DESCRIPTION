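Package: meromix
Title: Monitoring Pipelines for Permanently Stratified Lakes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for physical and microbiological monitoring of meromictic
    (permanently stratified) lakes from CTD casts, flow-cytometry event tables
    and meteorological station records. Implements a lake-specific density
    equation of state and the Schmidt stability index over a hypsometric
    curve, turbidity-based detection of the anoxygenic phototroph bacterial
    layer with the five-depth sampling rule, size/fluorescence gating and
    enumeration of purple and green sulfur bacteria phenotypes, and seasonal
    aggregation of weather series. A seeded synthetic-data generator emulates
    stratified casts, bacterial-layer seasons, cytometry event clouds and
    warm-season weather with known ground truth, so every pipeline stage is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lubridate,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
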