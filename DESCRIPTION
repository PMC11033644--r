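Package: painrecord
Title: Phenotyping Recorded Physical Pain in Mental-Health Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for studying how physical pain is
    documented in the free text of mental-health electronic health records.
    Provides a synthetic linked-EHR cohort generator, eligibility filtering,
    lexicon-based pain-mention detection with sentence segmentation, a
    deterministic rule engine that labels each mention as relevant or
    not-relevant (negated, form, misspelling, hypothetical, metaphorical),
    body-part gazetteer aggregation into seven anatomical regions,
    primary-care coded-pain flagging with primary/secondary overlap
    partitions, and association statistics (2x2 odds ratios with Wald
    intervals and incrementally adjusted logistic regression models).
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
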