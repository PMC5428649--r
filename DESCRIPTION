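Package: herbconnect
Title: Connectivity-Map Scoring and Network Propagation for
    Multi-Component Herbal Medicines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for interrogating the transcriptional activity of
    traditional-medicine compounds and their mixtures. Extracts up/down
    tag-set signatures from replicated treated-versus-vehicle expression
    matrices by fold-change filtering, scores signatures against a local
    collection of rank-ordered reference instances with a
    Kolmogorov-Smirnov-style connectivity score and permutation-based
    by-compound enrichment, and evaluates multi-component synergy by
    random walk with restart on a protein-interaction network: disease
    and drug-target seed sets are propagated to steady state, compared
    by an inner-product effect score, and standardised against random
    target sets of equal size. Includes synthetic-data generators with
    planted ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
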