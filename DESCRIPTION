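Package: nearmiss
Title: Decision-Grade Analytics for Hospital Near-Miss Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Converts raw hospital near-miss event logs into decision-grade
    safety intelligence through a three-level maturity pathway: standardized
    rates per exposure denominator (patient-days, doses, specimens, units,
    procedures) with near-miss-to-harm ratios; u-charts with the Laney U'
    overdispersion adjustment and run-rule signal detection; a severity-weighted
    Near Miss Index on the four-point consequence scale; 90- and 180-day
    organizational learning yields; and a deterministic interpretation matrix
    that maps joint trends in near misses, harm, and reporting volume to
    leadership guidance. Includes a seeded synthetic event-log generator with
    controllable overdispersion for method validation, and CSV/JSON reporting
    pipelines for monthly dashboards, unit trend cards, and quarterly
    prioritization briefs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
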