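Package: connectropy
Title: Information-Theoretic Random-Walk Measures for Weighted Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models a weighted undirected connectome as a stationary random
    walk on the connectivity graph and derives information-theoretic network
    measures from the resulting Markov chain. Global measures characterise the
    whole network (stationary entropy, mutual information between consecutive
    walk states, and erasure mutual information, which conditions on both past
    and future states); local measures decompose them per node (entropic
    surprise, mutual surprise, mutual predictability, erasure surprise).
    Includes the standard node strength, eccentricity and weighted clustering
    coefficient for comparison, log-curve fits between local and standard
    measures, generators for random, lattice, ring-lattice and small-world
    benchmark networks with uniform random weights, sweep experiments over
    edge count and network size, readers and writers for dense-matrix and
    edge-list connectivity files, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
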