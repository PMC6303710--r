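Package: wetgerm
Title: Wet-Thermal Time Modelling of Seed Germination Timing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for modelling seed germination phenology from
    constant-temperature laboratory trials and seedbed microclimate records.
    Computes classical germination indices (final percentage, mean
    germination time and rate, coefficient of variation, uncertainty,
    synchrony, time to percentile germination), fits per-percentile
    quadratic rate-versus-temperature curves, and applies a wet-thermal
    accumulation model (progress accrues only while soil water potential is
    at or above a base threshold) to hourly soil temperature and water
    potential series to predict field germination dates, including daily
    planting-date scans against a spring-germination cutoff. A synthetic
    data generator with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    readxl,
    withr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
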