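Package: visiolex
Title: Visually Sensitive Language Features from Timed Speech Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts visually sensitive language features from
    word-timestamped speech transcripts of picture-description and
    autobiographical tasks: corpus-calibrated lexical frequency of content
    words, word utterance latency and articulation rate decomposed from
    word timings, the spatial relational word ratio, and content-unit
    scores with once-per-sample counting and variant grouping. Provides
    Welch two-sample comparisons (from raw vectors or printed summary
    statistics), Bonferroni-controlled point-biserial screens of per-unit
    mention probabilities, and a ridge-penalized logistic classifier with
    leave-one-out cross-validation, ROC and AUC. A seeded synthetic-cohort
    generator produces feature-level and transcript-level two-group
    cohorts calibrated to published group profiles so every stage of the
    pipeline is testable without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
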