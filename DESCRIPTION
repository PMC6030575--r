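Package: dailyphq
Title: Joint Two-Level Factor Analysis of Daily Mood Ratings and Periodic
    Depression Questionnaires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating brief daily depressive-mood ratings against
    a periodic multi-item depression questionnaire in intensive longitudinal
    (ecological momentary assessment) designs. Fits, by full-information
    maximum likelihood, a joint model coupling a two-level confirmatory
    factor analysis of a daily 2-item measure (separating day-to-day from
    between-person variability in unbalanced clusters) with a single-level
    factor analysis of a 9-item questionnaire; computes level-specific
    composite (omega) reliabilities and the person-mean reliability of the
    daily composite; tests measurement invariance across demographic groups
    by likelihood-ratio comparison of constrained and unconstrained
    multiple-group fits; and predicts later outcomes from daily-summary
    features via seemingly unrelated regression. Includes a synthetic-cohort
    generator emulating the sampling structure of a remote mobile-health
    depression study so that every stage of the analysis is testable at desk
    scale without access to restricted trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
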