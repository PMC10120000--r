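Package: connperc
Title: Percolation Analysis of Brain Structural Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Targeted-attack percolation analysis of weighted structural
    connectomes. Reads edge-list and matrix connectomes carrying per-edge
    tract length and tract density, computes giant-cluster P(<k>) curves
    under sequential edge removal, evaluates the Giant Cluster Self
    Preference closed-form growth theory (Lambert-W) and its finite-size
    master equation, fits the self-preference parameter alpha to empirical
    attack curves, and simulates network growth under the Early Path
    Dominance model alongside Erdos-Renyi, preferential-attachment,
    small-world and spatial comparison graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    pracma,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
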