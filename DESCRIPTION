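Package: pathtopo
Title: Topology-Based Pathway Analysis of Two-Condition Gene Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Seven topology-based pathway analysis methods (SPIA, PRS, PWEA,
    TAPPA, DEGraph, TopologyGSA, clipper) for two-condition gene expression
    experiments, on a shared signed pathway-graph data model supporting mixed
    directed/undirected and parallel edges. Includes KGML and edge-list
    pathway import, pathway editing and reduction, RNA-Seq count
    normalization (TMM and median-of-ratios) with a moderated-t differential
    expression engine, graph machinery (maximal cliques, moralization,
    triangulation, junction trees, signed Laplacians), a uniform result
    container with Benjamini-Hochberg adjustment, Graphviz DOT export of
    per-gene statistics, and synthetic data generators so every component is
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    DESeq2,
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
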