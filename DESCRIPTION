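Package: gsifam
Title: Family Structure Effects on Genetic Stock Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for genetic stock
    identification (GSI) with microsatellite-style codominant markers.
    Generates synthetic population baselines with controlled divergence
    and full-sibling family structure, estimates mixture proportions by
    maximum-likelihood EM (mixed stock analysis) with bootstrap confidence
    intervals, performs individual assignment and leave-one-out
    self-assignment, runs 100 percent simulation power tests, and
    orchestrates factorial experiments quantifying how family structure
    and baseline sample size bias both true GSI accuracy and the standard
    accuracy tests. Includes Weir-Cockerham F-statistics with permutation
    tests, unbiased gene diversity, GENEPOP input/output and QC summaries.
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
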