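Package: synergyfield
Title: State-Dependent Mapping of Spinal Interneuron Muscle Fields onto
    Muscle Synergies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for motor-control electrophysiology relating
    the spiking of spinal interneurons to hindlimb muscle coordination.
    Computes spike-triggered averages (SpTA) of multichannel EMG and
    per-unit muscle fields (mean percentage increments of post-spike
    facilitation), extracts muscle synergies and activation coefficients by
    multi-restart non-negative matrix factorization with an R-squared based
    model-order rule, matches fields to synergies within and across
    optogenetic stimulation conditions by maximal scalar product and
    optimal assignment, classifies across-condition changes of a unit's
    preferred synergy into merging, unmatched or preserved forms via
    non-negative least squares, and correlates per-locus firing rates with
    synergy activation amplitudes. Includes a spike/EMG co-simulator with
    planted synergies, spike-locked muscle-field kernels and
    condition-dependent rewiring, used as ground truth for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    clue,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
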