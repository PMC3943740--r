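Package: netpharm
Title: Network Pharmacology Toolkit for Disease Networks and
    Compound-Target Screening
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assembles disease protein-protein interaction networks from
    seed genes and known drug targets (PPI, extended PPI, core PPI),
    prioritizes putative drug targets by five topological measures
    (degree, clustering coefficient, betweenness, bridging and closeness
    centrality) with predictive-rate evaluation against known targets,
    filters compound catalogs by Lipinski's rule of five, calls effective
    compound-target interactions from docking scores with a dual cutoff
    (per-target positive-drug cutoff and a -5 kcal/mol floor), builds
    bipartite compound-target networks with per-edge provenance, and
    summarizes networks (components, per-herb target coverage,
    hypergeometric pathway enrichment). Includes a seeded synthetic-data
    generator emulating a scale-free interactome with planted targets and
    a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    optparse,
    yaml,
    fgsea,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
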