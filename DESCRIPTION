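Package: msforest
Title: Multistate Survival Forests and Recursively Imputed Survival Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonparametric machinery for progressive and illness-death
    multistate time-to-event processes: long-format event-history data
    handling under the separate (transition-specific) approach,
    Nelson-Aalen and Aalen-Johansen estimators with delayed entry,
    extremely randomized multistate trees with log-rank splitting,
    multistate random survival forests (MSRSF), multistate recursively
    imputed survival trees (MSRIST) with ensemble-conditional imputation
    of censored sojourns, inverse-probability-of-censoring-weighted Brier
    scores, concordance indices, random-daughter variable importance, and
    a cohort simulator with known transition intensities for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
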