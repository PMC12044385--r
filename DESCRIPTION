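Package: cultnet
Title: Removal Robustness and Social Learning Simulations on Animal Social Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for studying how the loss of individuals affects
    information flow in female mammalian social networks. Generates multi-wave
    synthetic weighted association networks emulating baboon-, dolphin- and
    elephant-like structural profiles; computes group-level structure (modularity,
    transitivity, density, weighted path length) and individual centralities;
    measures weighted global efficiency under stepwise random, age-based and
    centrality-targeted node removal; and runs an agent-based model of
    age-structured social learning and innovation on NK rugged fitness
    landscapes, comparing removal scenarios against paired no-removal baselines
    across a grid of innovation rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
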