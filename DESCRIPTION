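Package: geovalid
Title: Validity Analysis of GPS-Derived Mobility Measures
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating GPS-derived counts of places visited against
    self-report measures. Implements stay-point (stop) detection on 1 Hz GPS
    trajectories with movement-anomaly screening, rule-based promotion of stops
    to place visits, and daily/weekday/weekend aggregation to the Number of
    Places Visited (NPV). Provides unit-weighted Active- and Sedentary-Lifestyle
    factor scores from standardized questionnaire indicators, pairwise-complete
    correlation panels with Fisher-z confidence intervals, split-plot general
    linear models with sequential (Type-I) sums of squares, planned orthogonal
    method contrasts and stratum-specific error terms, and a fully seeded
    synthetic-data generator (latent factors, itineraries, noisy trajectories,
    recall-error self-reports, MCAR missingness) for property-based validation
    of the whole chain.
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
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
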