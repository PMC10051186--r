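Package: wearexpo
Title: Personal Air-Pollution Exposure Analysis from Wearable Sensors and GPS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing personal exposure to air pollutants measured
    by wearable low-cost sensors (particulate matter, nitrogen dioxide, black
    carbon) together with GPS tracks. Provides curation of per-minute series
    (windowed peak-artifact removal, range filtering, particle-size
    consistency, electrochemical warm-up trimming, black-carbon noise floor,
    GPS speed filtering), automatic microenvironment assignment with a
    multi-view stacking classifier and rule-based post-processing (grid
    density stop segmentation, night-time home identification, label
    smoothing), environment-stratified exposure summaries with WHO guideline
    comparison, a multi-metric sensor-versus-reference performance index, and
    a synthetic campaign generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
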