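Package: snapclone
Title: Stochastic Gene Expression in Growing, Age-Structured Cell Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing stochastic biochemical dynamics in
    exponentially growing clonal cell populations. Provides division-time
    distribution models with Euler-Lotka growth rates, ancestral
    division-time laws and population, history and forward-lineage age
    distributions; an exact event-driven population simulator (first
    division algorithm) combining Gillespie chemistry within cells with
    age-dependent or expression-coupled division and binomial partitioning
    at division; lineage-tree statistics for the forward, history and
    age-sorted snapshot ensembles, including Fisher's reproductive value
    and a permutation test of the ergodic principle that links histories
    to age-sorted snapshots; and analytic molecule-number distributions
    for the birth-death and bursty protein expression models under
    arbitrary division-time distributions, cross-checked against a
    truncated master-equation solver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
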