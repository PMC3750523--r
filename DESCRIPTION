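Package: multinoise
Title: Delayed Stochastic Simulation of Gene Expression with Protein
    Multimerization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact event-driven stochastic simulation of gene expression
    with delayed product release, supporting gamma-distributed
    transcription initiation intervals, protein multimerization (homomers
    of arbitrary order and heterodimers), and multimer-regulated genetic
    toggle switches. Provides the statistics needed to study how
    multimerization shapes the abundance and temporal variability of
    functional protein complexes: mean and squared-coefficient-of-variation
    noise gains relative to a null model, monomer-multimer
    cross-correlation and its half-life, toggle-switch mean switching
    times, maximum-likelihood fitting of gamma and hypoexponential models
    to transcription-interval samples, and population-level summaries of
    per-gene protein statistics by essentiality and subunit count.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    jsonlite,
    yaml,
    fitdistrplus,
    tibble
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    arrow,
    optparse
Config/testthat/edition: 3
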