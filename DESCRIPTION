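Package: hubtrace
Title: Key-Regulator Discovery in Protein Interaction Networks by
    Hierarchical Motif Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a key-regulator discovery pipeline for
    protein-protein interaction (PPI) networks: topological
    characterization (degree spectra, clustering and neighborhood
    connectivity profiles, closeness/betweenness/eigenvector
    centralities, power-law fits), recursive multi-level community
    decomposition by modularity optimization down to triangle motifs
    G(3,3), tracing of high-degree hubs through every hierarchical
    level to nominate key regulators, a fold-change and significance
    filter for quantitative proteomics ratio tables, and a
    list-intersection step that pinpoints common candidate targets.
    Ships synthetic generators (deterministic hierarchical model,
    planted multi-level hierarchy with designated hub regulators,
    random and preferential-attachment controls, quantitation tables
    with planted deregulation) so that every stage is testable against
    known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
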