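Package: tetranet
Title: Tetramer-Compatible Motif Analysis of Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying small connection patterns in undirected
    protein-protein interaction networks with self-interactions, motivated
    by the quartet model of MADS-domain transcription factor function. The
    package enumerates a complete catalogue of connected 2-4 node patterns
    (self-loops allowed) by exhaustive isomorphism reduction, performs exact
    induced and embedded subgraph censuses, assesses over-representation
    against a degree-preserving edge-switching null model with empirical
    p-values, tests the association between tetramer-compatible subgraphs
    and tissue co-expression of the encoding genes, lists prospective
    tetramers, and retrodicts candidate redundant proteins. A synthetic-data
    generator with planted motifs supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
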