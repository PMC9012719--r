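Package: esindicator
Title: Ecosystem Service Indicator Framework for Supply-Demand Assessment
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Ecosystem Service Indicator (ESI), a composite
    0-100 score of whether ecosystem-service supply meets demand across
    spatial units and monitoring instances. Implements the three dimensions
    scope (F1), frequency (F2) and amplitude (F3, via normalized-sum and
    mean-of-excursions aggregates), sharp and fuzzy failure objectives,
    three combination methods (a CCME water-quality-index style
    root-mean-square and two adjusted geometric forms) at three levels of
    evidence, a Monte-Carlo simulator of reliability tables under
    controlled probability and range of failure with the study's discard
    rules, and analysis utilities (percentile summaries, correlations,
    subset analyses, binned grids) for characterising indicator behaviour.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
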