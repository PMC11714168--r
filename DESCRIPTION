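Package: InfilNet
Title: Cell Infiltration Scoring from Individualized Cell-Cell Crosstalk Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the relative infiltration of up to 86 cell types in a
    tumor or tissue sample from its bulk gene-expression profile. For each
    sample a weighted bipartite network linking cell types to Gene Ontology
    biological processes is built (edge weight = Jaccard overlap of the two
    gene sets times the median expression of their shared genes), projected
    onto a cell-cell crosstalk network, and each cell's centrality in that
    network is scored with a restarted random walk. Per-sample scores are
    log10-transformed and min-max normalized to a 0-1 infiltration score
    (InScore). Includes GMT gene-set handling, a cohort pipeline, linear
    risk-score evaluation from user-supplied coefficients, a synthetic-data
    generator for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
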