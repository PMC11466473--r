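Package: obkit
Title: Metric Backbones and Cross-Species orthoBackbones of Weighted
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for cross-species analysis of weighted gene interaction
    networks. Builds expression-filtered interaction layers from TPM tables
    and confidence-scored edge lists, extracts each layer's metric backbone
    (the shortest-path-sufficient subgraph obtained by removing semi-metric
    edges), and collapses the backbones of multiple species into an
    orthoBackbone using orthogroup membership with a one-to-many paralog
    rule. Also provides phylostratigraphy (ranking a rooted species tree
    into phylostrata and assigning orthogroups to their oldest clade), the
    transcriptome age index, node-connectivity features (degree centrality,
    PageRank) with conserved-versus-non-conserved comparisons and
    cross-validated conservation classifiers, an edge-rewiring null model,
    an orthoBackbone edge-disruption statistic for differentially expressed
    gene sets, and a seeded synthetic multilayer generator with planted
    ground truth so the whole pipeline is testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    ape,
    jsonlite,
    yaml,
    SummarizedExperiment,
    S4Vectors,
    randomForest,
    e1071,
    pROC
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
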