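Package: crnflow
Title: Chemical Reaction Network Expansion and Autocatalytic Hyperflow Queries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based expansion of chemical reaction networks (CRNs) from
    molecular graphs and graph-transformation rules in a GML dialect, search
    for shortest autocatalytic pathways by an exact integer linear programming
    hyperflow model on the directed multi-hypergraph, and post-annotation of
    pathway solutions with cofactor usage, carbon units fixed, and standard
    transformed Gibbs reaction energies. Includes a synthetic toy chemistry
    with a planted autocatalytic cycle and brute-force oracles so every stage
    is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
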