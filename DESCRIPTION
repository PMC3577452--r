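Package: sliceRec
Title: Gene Tree Reconciliation into Time-Sliced Species Trees and
    Supertree Amalgamation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Parsimony reconciliation of rooted gene trees into a
    time-sliced species tree under an extended event model covering
    duplications, losses, gains, horizontal transfers (with and without
    retention in the donor) and gene dormancy.  The dynamic program
    returns the minimal mapping cost, an explicit event tree with the
    tube path (mapping beta) of every gene-tree edge, and a stochastic
    k-best scenario DAG from which expectations of event counts and
    costs per species-tree tube are computed.  A companion supertree
    algorithm amalgamates a forest of gene trees by dynamic programming
    over a fixed family of candidate clades (basic trees with
    duplication/loss counting) followed by greedy assembly of the final
    species tree scored by reconciliation.  Includes a forest simulator
    with duplication, loss and within-slice transfer events, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
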