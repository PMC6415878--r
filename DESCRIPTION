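Package: barrettcca
Title: Cost-Consequence and Budget-Impact Modelling of Barrett's Esophagus
    Surveillance Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic model comparing narrow-band-imaging (NBI) guided
    targeted biopsy against high-definition white-light endoscopy with the
    Seattle protocol for surveillance of Barrett's esophagus, from an NHS
    England (or single-hospital) perspective. Implements the diagnostic
    decision tree, a 6-month-cycle Markov model of dysplasia progression,
    micro-costing and tariff-based costing with capital-equipment
    amortization, cost-consequence and budget-impact tables, incremental
    cost-effectiveness ratios, deterministic one-way sensitivity analysis
    (tornado), and an individual-patient microsimulation used as a
    verification oracle for every cohort-level expectation.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
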