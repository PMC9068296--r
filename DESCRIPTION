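Package: netpharm
Title: Network Pharmacology Pipelines for Multi-Component Herbal Compound Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for rule-based ADMET/drug-likeness screening of metabolite
    panels, probability filtering of predicted compound-target interactions,
    construction of tripartite target-pathway-disease networks, one-mode
    projection to weighted target-target graphs, Louvain functional-module
    detection, module-to-disease contribution scoring, and key-target ranking
    by an integrated centrality (the mean of min-max normalized degree,
    betweenness, closeness and eigenvector centralities within each module).
    Includes a synthetic-data generator with planted block structure, hubs and
    disease-concentrated pathways so every pipeline stage can be validated
    against known ground truth, plus deterministic exporters to Pajek, GraphML,
    SIF and edge-list formats.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    Matrix,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
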