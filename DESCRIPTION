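Package: crowdscreen
Title: Consecutive-Agreement Aggregation, Evaluation and Simulation for
    Crowdsourced Citation Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for crowdsourced title-abstract screening of search
    results in evidence synthesis. Aggregates ordered per-record
    classification streams into collective decisions under a configurable
    consecutive-agreement policy (k identical verdicts in a row), scores
    collective decisions against a reference standard (sensitivity,
    specificity, crowd consensus and subgroup consensus, missed-study
    reports, forward citation recovery), routes decisions through
    sensitivity-, speed- and specificity-maximising author workflows with
    workload accounting, and simulates synthetic crowds (corpora with
    planted prevalence and title-only records, contributor pools with
    per-classification accuracies, qualification-test gating, and an
    event-driven screening loop under a deadline) so every stage is
    testable without platform data.
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
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
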