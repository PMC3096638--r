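Package: netcurve
Title: Characteristic Curves of Large Networks from Breadth-First Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps a network onto a pair of planar point clouds (the BFS-tree
    and BFS-graph embeddings) whose point sequence forms a nondecreasing
    "characteristic curve" that fingerprints the network's structure.
    Provides the two-queue breadth-first-search mapping, closed-form and
    general analytic curves for configuration-model random graphs (regular,
    Poisson, power-law) and lattice-embedded random regular graphs, a
    curve-area graph distance with alignment rules, a search-efficiency
    clustering measure against degree-matched random counterparts, a
    median-distance network classifier, and an end-to-end pipeline that
    ranks growth models (duplication-mutation-complementation,
    duplication-mutation-random, linear preferential attachment, Poisson
    random graphs) against a target network such as a confidence-scored
    protein-protein interaction map.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
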