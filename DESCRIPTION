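Package: seekr
Title: Markov and N-Gram Analysis of Coded Health Information Search Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing health information search behaviour recorded
    as sequences of coded search activities. Sessions are transcribed with a
    fixed 18-code scheme spanning the querying, accessing, evaluating, using
    and discarding stages of a search. The package scores a health terminology
    familiarity questionnaire into L1/L2/L3 familiarity labels, estimates
    first-order Markov transition matrices per familiarity group, compares
    groups with a Pearson-type chi-square test on transition counts, fits
    Witten-Bell smoothed n-gram models of activity sequences and selects the
    model order by held-out perplexity, mines frequent fixed-length activity
    patterns with behavioural category tags, and simulates labelled synthetic
    session corpora and questionnaires for end-to-end pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
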