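Package: stratseq
Title: Multi-Dimensional Stratified Sequestration of Patient Cohorts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions batches of de-identified patient imaging metadata
    into an open (~80%) and a sequestered (~20%) data commons while
    balancing the joint distribution of demographic variables (age group,
    race, sex at birth, ethnicity, COVID-19 status, and primary image
    modality). Patients are grouped into strata -- unique combinations of
    one category per variable -- and each stratum is split by randomized
    rounding, so every demographic cross-section is carried into both
    commons at close to the target fraction. A persistent assignment
    registry keeps all longitudinal data of a patient in a single commons
    across intake batches. Includes a synthetic cohort generator with
    configurable marginal distributions, and an evaluation framework:
    scaled difference from expectation, multi-trial prevalence summaries,
    one-tailed Mann-Whitney U comparison against naive randomization, and
    Holm-Bonferroni correction for multiple comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    readr,
    jsonlite,
    rlang,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
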