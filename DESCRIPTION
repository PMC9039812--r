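Package: routinewatch
Title: Anomaly Detection for Daily Routines from Ambient Smart-Home Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for ambient assisted living: reads timestamped
    smart-home sensor event logs (passive-infrared motion, wall plugs,
    water meters), cleans them (duplicate removal, gap detection,
    exclusion calendars), segments motion events into room-occupancy
    intervals, extracts per-activity time-window features (duration,
    visit frequency, appliance usage), learns per-resident normal
    duration ranges with distribution-free Chebyshev thresholds, and
    classifies each day's activity as normal, unusually short, unusually
    long, or not present. Includes a notification renderer with
    preference-based routing, trial-report aggregation, and a synthetic
    single-resident apartment simulator with ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
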