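Package: bivouac
Title: Agent-Based Simulation of Army-Ant Foraging and Living-Bridge Formation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based simulator of collective foraging in army ants on a
    bounded lattice. Major and Minor ant agents search, transport food and
    communicate through a two-layer pheromone field in which deposited ground
    pheromone evaporates into a diffusing space layer that agents perceive.
    Altruistic chain formation over impassable ditches produces living
    bridges whose stability follows saturating entry and pheromone-coupled
    leaving probability models. Includes scenario presets over feeding-spot
    size ratios, deterministic seeded runs, per-tick occupancy and bridge
    metrics, depletion-order summaries, and colony-size sweeps with spatial
    group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
LinkingTo: Rcpp
Config/testthat/edition: 3
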