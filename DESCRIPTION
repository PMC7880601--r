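Package: chronoscreen
Title: Chronopharmacology Screening Analysis for Time-of-Day Drug Efficacy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for high-throughput chrono-pharmacological
    screens in circadian-synchronized cell cultures: plate-level quality
    control (Z'-factor), normalized percent inhibition, four-parameter
    logistic IC50 fitting with out-of-range capping, phase-normalized
    temporal IC50 profiles, a from-scratch JTK-Cycle nonparametric
    rhythmicity test with exact null distributions, damped-cosinor analysis
    of circadian reporter traces, drug-target expression-phase
    cross-referencing, FUCCI cell-cycle synchrony metrics, and tumor
    growth-rate comparison. A synthetic-data generator reproduces the
    staggered dexamethasone-synchronization screen design for testing and
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    digest,
    minpack.lm,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    readr
Config/testthat/edition: 3
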