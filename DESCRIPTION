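Package: warpnet
Title: Disease-Gene Prioritization by Random Walks on Curvature- and
    Prior-Warped Interaction Networks
Version: 0.1.0
Authors@R:
    person("Warpnet", "Developers", email = "warpnet@example.org",
           role = c("aut", "cre"))
Description: Prioritizes disease genes by diffusing omics-derived gene
    scores over a protein-protein interaction network that has been
    warped by two features: augmented Forman-Ricci edge curvature (an
    internal, topology-derived feature) and smoothed prior knowledge (an
    external feature spread by a restart Markov kernel). Includes readers
    for plain, STRING-style and BioGRID-style edge lists, initial score
    computation from case/control expression matrices (per-stratum
    t-tests, Fisher combination, Z transform), ranking metrics (average
    precision, precision at k) with paired significance testing, and a
    synthetic-data generator with planted cliques and hubs for end-to-end
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
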