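Package: logiprofile
Title: Personalization of Stochastic Boolean Network Models with Multi-Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tailors generic asynchronous Boolean network models to individual
    tumor profiles. Parses logical models in a MaBoSS-dialect text format,
    simulates them as continuous-time Markov chains with a Gillespie algorithm
    (with an exact master-equation oracle for small models), classifies gene
    expression distributions (Hartigan dip test, bimodality index, kurtosis)
    to normalize or binarize them, infers functional effects from mutation and
    copy-number records, merges all data types into per-patient node constraints
    and transition rates, and stratifies cohorts on the resulting phenotype
    probabilities. Ships seeded synthetic-data generators so the full pipeline
    runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    mclust,
    e1071,
    generics,
    ggplot2,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot,
    survival,
    jsonlite,
    optparse
Config/testthat/edition: 3
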