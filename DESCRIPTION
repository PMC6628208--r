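Package: netweaver
Title: Merge Gene and Protein Target Lists into Cytoscape Network and
    Attribute Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates heterogeneous gene/protein target lists (DamID
    screens, differential-expression lists, proteomic screens) into
    Cytoscape-ready network and node-attribute CSV files. Each uploaded
    list becomes a wheel network with its core gene at the hub; merged
    wheels are interconnected by shared targets. Identifiers are updated
    and curated genetic/physical interactions retrieved through a
    pluggable resolver (an InterMine web service or deterministic local
    tables for offline use). Downstream analyses include duplicate-edge
    removal, iterative terminal-node/linear-path filtration, co-target
    partitioning of targets by the set of core genes regulating them,
    and exact hypergeometric enrichment of highly expressed genes.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
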