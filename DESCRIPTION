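Package: paircoex
Title: System-Level Effects of Third-Party Species on Pairwise Coexistence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric and probabilistic analysis of pairwise species
    coexistence within multispecies generalized Lotka-Volterra systems under
    environmental uncertainty. Computes feasibility domains and their
    normalized spherical measures, projections of feasibility cones onto
    pair planes, partitions of the growth-rate sphere into non-invadable
    composition regions, and the system-level coexistence indicators:
    projection contribution, long-term effect, simulated short-term effect,
    buffering effect, and their experimental analogues estimated from
    replicated monoculture/co-culture/poly-culture final-density tables.
    Includes seeded generators for random interaction matrices and synthetic
    community experiments, a fixed-step Runge-Kutta integrator for batch
    simulation, and tidy summaries with plotting helpers.
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
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
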