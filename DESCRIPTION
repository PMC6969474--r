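Package: CoexPreserve
Title: Differential Coexpression Network Preservation Between Conditions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds per-condition binary gene coexpression networks from
    bulk RNA-seq counts by hard-thresholding Pearson correlations on both
    effect size and significance, computes node connectivity and clustering
    coefficient, and compares their distributions between two experimental
    conditions with a sample-permutation preservation test. Also provides
    Benjamini-Hochberg FDR selection of differentially expressed genes,
    hypergeometric (Fisher one-sided) gene-set overrepresentation analysis,
    delta-delta-Ct qPCR relative expression with a likelihood ratio test for
    a group effect, and a seeded synthetic-data generator with planted
    coexpression modules for end-to-end testing of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: NetworkInference, GeneExpression, Transcriptomics,
    DifferentialExpression, GraphAndNetwork
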