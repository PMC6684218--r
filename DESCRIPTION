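Package: adrsignal
Title: Adverse Drug Reaction Signal Detection from Health Forum Posts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pharmacovigilance signal-generation pipeline for
    social health network posts. Builds per-drug corpora by keyword matching,
    extracts adverse drug reaction (ADR) and indication mentions with a
    feed-forward neural sequence tagger over skip-gram word embeddings,
    normalizes mentions to grouped medical concepts via a lemma-based ranked
    retrieval index, computes proportional reporting ratios (PRR) from
    unique-user contingency counts, calibrates a signal threshold against an
    empirical negative-control distribution, and performs time-to-detection
    analysis against literature report dates. Includes a synthetic forum-corpus
    generator with planted association strengths so every stage is testable
    end to end.
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
    stringr,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
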