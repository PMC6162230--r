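Package: pdpa
Title: Spatial Prisoner's Dilemma with Probabilistic Abstention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seeded Monte Carlo simulator for the spatial prisoner's dilemma
    with probabilistic abstention, a hybrid of the classic prisoner's dilemma
    and the optional (voluntary-participation) prisoner's dilemma. Agents live
    on a toroidal square lattice with von Neumann neighbourhoods and carry a
    binary strategy (cooperate or defect) together with a discretized
    probability of abstaining from any single interaction; an abstained
    interaction pays both parties the loner's payoff. The package provides
    synchronous best-neighbour imitation and asynchronous Fermi-rule imitation
    dynamics with a compiled core, population observables (effective
    cooperation, abstention, strategy composition, abstention-level occupancy),
    ensemble averaging, temptation and loner-payoff parameter sweeps, and a
    small command-line driver. All randomness flows through R's seeded random
    number generator, so every run is bit-reproducible.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tibble,
    jsonlite,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
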