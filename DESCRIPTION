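Package: netrewire
Title: Temporal Gene Coexpression Networks from First-Order Partial
    Correlations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers condition-specific gene coexpression networks from
    multi-timepoint expression data using first-order Spearman partial
    correlations, and quantifies how the network is rewired across an
    ordered treatment time course. Provides per-gene differential
    expression screening to define the network node set, permutation-null
    validation of edge counts, topology summaries (degree distributions,
    largest connected component, mean shortest path, global clustering),
    classification of genes into hub/bottleneck roles by Tukey outlier
    fences on degree and betweenness centrality, and rewiring summaries
    (conserved links, category transitions, degree-change patterns). A
    synthetic-data generator with planted Gaussian graphical structure,
    controlled inter-timepoint edge overlap and optional mean shifts
    provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    MASS,
    S4Vectors,
    SummarizedExperiment
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
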