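Package: bnctrl
Title: Target Control of Boolean Networks via Value Percolation and Trap Spaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identification of minimal node, edge and mixed control strategies
    in Boolean networks. Networks are read from the bnet text format and held
    in disjunctive normal form. Control strategies are found by value
    percolation, either directly to a target subspace or to "selected" trap
    spaces that contain only attractors inside the target; the latter route
    finds interventions that classical percolation-based methods miss and
    never introduces new attractors. Includes exact trap-space enumeration,
    attractor computation via terminal strongly connected components of the
    synchronous, asynchronous or generalized asynchronous state transition
    graph, a consistency calculus for mixed node/edge intervention sets, and
    a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
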