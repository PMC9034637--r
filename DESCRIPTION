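Package: cortexmc
Title: Semi-Grand-Canonical Lattice Monte Carlo Simulation of the Actomyosin Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained Metropolis Monte Carlo simulator of a two-dimensional
    actomyosin cortex exchanging G-actin, actin crosslinkers and myosin motors with a
    finite cytoplasmic reservoir. Implements directional actin polymerization and
    pointed-end depolymerization on a square lattice, crosslinker-mediated network
    assembly, myosin load accumulation with threshold detachment and load
    redistribution, an exact small-system Markov-chain oracle, time calibration
    against an 18-minute equilibration reference, and observables for occupancy,
    filament size distributions, treadmilling velocity, network statistics, cortical
    tension and Fourier oscillation-period analysis. Trajectories, censuses and
    parameter sweeps are returned as tibbles; results have tidy(), glance() and
    autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
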