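Package: flarecco
Title: Case-Crossover Analysis of Pain Flares from Daily Symptom Diaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting pain flares in daily mobile-health symptom
    diaries and estimating, by a within-person case-crossover design, how
    short-term changes in self-reported symptoms and accelerometer-derived
    sleep and activity relate to flare onset. Implements three progressively
    stringent numeric flare definitions (above personal median, above
    threshold, move above threshold), construction of 3-day hazard and
    control windows with mean and intraindividual-standard-deviation
    exposure summaries, and exact conditional logistic regression for
    multi-case matched sets with cluster-robust sandwich standard errors.
    Includes a synthetic diary and actigraphy cohort generator with planted
    exposure effects for validating the full pipeline against known truth.
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
    survival,
    withr,
    knitr
Config/testthat/edition: 3
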