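Package: CPMap
Title: Community Detection in Signed Networks via the Signed Map Equation
    and the Constant Potts Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering community structure in networks whose
    edges carry positive (affinity) or negative (antagonism) weights. The
    package evaluates partitions with a signed Map Equation (SiMap) that
    reweights random-walk flows so that external negative ties trap the
    walker inside its module while internal negative ties expel it via
    uniform teleportation; optimizes a signed Constant Potts Model (CPM)
    with a Louvain algorithm plus recursive refinement; and selects the CPM
    resolution by minimizing the SiMap description length across the
    resolution spectrum (the CPMap algorithm). Baseline objectives (signed
    modularity, the unsigned map equation), the Normalized Variation of
    Information partition metric, and signed / coupled LFR benchmark
    generators with ground-truth partitions are included, together with
    edge-list preprocessing for raw directed signed networks and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    optparse,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
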