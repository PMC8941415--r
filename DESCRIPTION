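Package: flocksim
Title: Stochastic Neighbour Choice and Group Cohesion in Collective Motion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Spatially explicit, asynchronous (event-driven) agent-based
    simulation of collective motion in which each organism interacts with k
    neighbours chosen uniformly at random from its K nearest visible
    neighbours. Provides the epsilon-graph cohesion parameter C and cluster
    count Nc, windowed directed attraction-interaction network analysis
    (reachability, mutually reachable sub-groups, network parameter Np),
    mean-field stochastic differential equations for the polarization order
    parameter under pairwise versus averaging interactions, and replicate
    sweep orchestration with a cohesion saturation-threshold estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
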