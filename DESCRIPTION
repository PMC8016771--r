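Package: endovoices
Title: Priority Statistics and Text Mining for Rare-Disease Patient Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for multilingual rare-disease patient
    surveys: three-point priority-rating statistics (paired t-tests, one-way
    ANOVA with Bonferroni-corrected post-hoc pairwise tests), topic discovery
    on free-text answers via TF-IDF-weighted non-negative matrix
    factorisation with TC-W2V coherence-based selection of the number of
    topics, and distinctive-phrase extraction per disease group with the
    KLIP metric (Kullback-Leibler informativeness and phraseness). Includes
    a synthetic survey-cohort and corpus generator so every stage is
    testable without access to raw response data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    Matrix,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
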