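Package: gliaCCC
Title: Differential Glia-Neuron Cell-Cell Communication Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers altered glia-to-neuron cell-cell communication from annotated
    single-nucleus RNA-seq count matrices. Aggregates counts to sample-by-cell-type
    pseudobulk, performs case-versus-control Wald-type differential expression with an
    optional sex covariate, identifies differential ligand-receptor candidates against a
    prior interaction network, scores ligand activity from regulatory-potential priors,
    prioritizes ligand-receptor-target triples by weighted aggregation of min-max-scaled
    metrics, applies a dual Pearson/Spearman correlation filter, intersects cohorts into
    high-confidence interaction sets, quantifies cell-type specificity with Jaccard
    similarity, identifies signaling mediators by minimal-cost receptor-to-target paths
    in a weighted signaling network, and scores transcription factor and pathway activity
    with a jointly fitted multivariate linear model. Includes a negative-binomial
    synthetic-data generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
biocViews: SingleCell, Transcriptomics, GeneExpression, NetworkInference, CellBiology
RoxygenNote: 7.3.3
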