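Package: screenval
Title: Training-Data Valuation for High-Throughput Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns importance scores to individual compounds in
    high-throughput screening (HTS) datasets using five training-data
    valuation engines (MVS-A gradient tracking in boosted trees, KNN
    Shapley values, frozen-structure leaf influence, TracIn checkpoint
    gradients, and reinforcement-learning value estimation), and applies
    those scores to three workflows: importance-driven active learning
    over a compound library, false/true-positive triage of primary-screen
    actives, and importance-guided undersampling of the inactive majority
    class. Includes a synthetic screen generator with planted false
    positives, early-recognition ranking metrics (BEDROC, enrichment
    factor, top-k precision, average precision), and a paired
    rank-test comparison harness.
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
    kernlab,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
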