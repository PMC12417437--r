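Package: airqa
Title: Quality Assurance and Campaign Analysis for Small-Form Air-Quality
    Sensor Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for running low-cost air-quality monitoring campaigns at
    institutional sites such as hospital campuses. Implements a four-step
    validation pipeline for 15-minute particulate-matter sensor data
    (completeness criteria, meteorology masking, static-data detection and
    median-absolute-deviation outlier exclusion), data-capture accounting,
    a passive NO2 diffusion-tube triplicate workflow with accuracy checks
    against reference monitors, WHO air-quality-guideline exceedance
    statistics, diurnal/weekly/monthly time-variation profiling, and
    month-matched baseline versus follow-up intervention comparison with
    Welch's t-test. Includes a seeded synthetic-data generator for
    multi-site sensor networks, meteorology, fault injection and tube
    campaigns so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
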