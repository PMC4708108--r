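Package: pkbasins
Title: Basin Hopping Graphs and Folding Kinetics for Pseudoknotted RNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Coarse-grains the folding landscape of an RNA molecule over
    genus-1 pseudoknotted secondary structures (H-, K-, L- and M-type
    pseudoknots) into a basin hopping graph: local minima connected by
    direct saddles estimated with a pseudoknot-aware findpath heuristic.
    Provides exact flooding of small landscapes, classification of
    pseudoknots by the topological genus of chord diagrams, a pluggable
    additive energy model with per-component pseudoknot penalties,
    continuous-time Markov chain folding kinetics with quasi-steady-state
    model reduction, and extraction of optimal refolding paths by minimax
    peak energy or maximum-likelihood trajectory criteria.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    yaml,
    jsonlite,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
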