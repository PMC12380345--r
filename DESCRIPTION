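Package: graip
Title: Random Graphs with Graphlet Frequency Bounds from Probabilistic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates random graphs whose degree distribution and graphlet
    (order 3-5) frequencies lie within statistical bounds estimated from a
    probabilistic (uncertain) target network, such as a protein-protein
    interaction network with per-edge confidence scores. The target envelope
    is estimated by Monte-Carlo sampling of possible worlds; graphs are then
    grown incrementally with an exact incremental graphlet-counting engine,
    so that counts are updated after each single-edge or single-node edit
    without a full recount. Also provides a configuration-model plus
    simulated-annealing baseline, and kernel-based ensemble comparison
    metrics (maximum mean discrepancy and randomness spread ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
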