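Package: trialops
Title: Operations Engine for Remote Weight-Management Trials with
    Contingency-Management Incentives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for running the operational core of a fully remote,
    incentive-based weight-management trial: ingestion of cellular-scale
    weight transmissions and daily dietary logs, automated screening of
    anomalous weights against a chained reference (with manual reference
    resets), weekly per-arm adjudication of dietary-logging and weight
    criteria across trial phases, holiday-aware scheduling of incentive and
    motivational text messages with delivery-receipt accounting and retry
    logic, and operational summary reporting. A synthetic-cohort simulator
    generates realistic adherence, errant-weight, and delivery-failure
    streams so the entire pipeline can be exercised end to end without
    participant data.
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
    lubridate,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
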