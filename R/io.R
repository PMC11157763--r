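#' Read annotated counts from MatrixMarket plus TSV sidecars
#'
#' Expects a genes-as-rows coordinate MatrixMarket file (plain or gzipped), a
#' one-column (or headered \code{gene}) genes TSV, and a cells TSV with
#' columns \code{barcode}, \code{sample_id}, \code{condition},
#' \code{cell_type}, \code{sex}.
#'
#' @param mtxPath,genesPath,cellsPath file paths.
#' @return A validated \linkS4class{CCCExperiment}.
#' @export
readCounts <- function(mtxPath, genesPath, cellsPath) {
    con <- if (grepl("\\.gz$", mtxPath)) gzfile(mtxPath) else mtxPath
    if (methods::is(con, "connection"))
        on.exit(tryCatch(close(con), error = function(e) NULL), add = TRUE)
    m <- Matrix::readMM(con)
    if (!methods::is(m, "dMatrix")) m <- m * 1   # pattern/logical dialects
    m <- methods::as(m, "CsparseMatrix")
    if (any(m@x != round(m@x)) || any(m@x < 0))
        stop("count matrix entries must be non-negative integers")
    genes <- utils::read.delim(genesPath, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    if (identical(genes[1], "gene")) genes <- genes[-1]
    cells <- utils::read.delim(cellsPath, stringsAsFactors = FALSE)
    need <- c("barcode", "sample_id", "condition", "cell_type", "sex")
    miss <- setdiff(need, colnames(cells))
    if (length(miss))
        stop(sprintf("cells table is missing column(s): %s",
                     paste(miss, collapse = ", ")))
    if (nrow(m) != length(genes))
        stop(sprintf("dimension mismatch: %d matrix rows vs %d genes",
                     nrow(m), length(genes)))
    if (ncol(m) != nrow(cells))
        stop(sprintf("dimension mismatch: %d matrix columns vs %d cells",
                     ncol(m), nrow(cells)))
    if (anyDuplicated(genes)) stop("duplicate gene ids")
    if (anyDuplicated(cells$barcode)) stop("duplicate cell barcodes")
    m <- methods::as(m, "CsparseMatrix")
    rownames(m) <- genes
    CCCExperiment(m, cells)
}

#' Write annotated counts as MatrixMarket plus TSV sidecars
#'
#' @param data a \linkS4class{CCCExperiment}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths written.
#' @export
writeCounts <- function(data, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "cells.tsv"))
    m <- SummarizedExperiment::assay(data, "counts")
    Matrix::writeMM(methods::as(m, "CsparseMatrix"), paths[1])
    writeLines(rownames(data), paths[2])
    cd <- as.data.frame(SummarizedExperiment::colData(data))
    cd$barcode <- rownames(cd)
    cols <- c("barcode", "sample_id", "condition", "cell_type", "sex")
    utils::write.table(cd[, cols], paths[3], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(paths)
}

.PRIOR_FILES <- c(lr = "lr_network.csv", rp = "regulatory_potential.csv",
                  se = "signaling_edges.csv", tf = "tf_regulons.csv",
                  pw = "pathway_weights.csv")

#' Write a prior knowledge bundle as five CSV files
#'
#' @param prior a \linkS4class{PriorKnowledge}.
#' @param dir output directory.
#' @return Invisibly, the file paths.
#' @export
writePrior <- function(prior, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- file.path(dir, .PRIOR_FILES)
    utils::write.csv(lrNetwork(prior), p[1], row.names = FALSE)
    rp <- regulatoryPotential(prior)
    long <- data.frame(ligand = rep(rownames(rp), ncol(rp)),
                       gene = rep(colnames(rp), each = nrow(rp)),
                       potential = as.vector(rp))
    long <- long[long$potential > 0, ]
    utils::write.csv(long, p[2], row.names = FALSE)
    utils::write.csv(signalingEdges(prior), p[3], row.names = FALSE)
    utils::write.csv(tfRegulons(prior), p[4], row.names = FALSE)
    utils::write.csv(pathwayWeights(prior), p[5], row.names = FALSE)
    invisible(p)
}

#' Read a prior knowledge bundle from five CSV files
#'
#' Validates all invariants: signaling weights in (0, 1], regulon modes in
#' \{-1, +1\} with unique (TF, target) pairs, unique (pathway, gene) pairs;
#' violations are reported with their row number.
#'
#' @param dir directory containing the five CSVs written by [writePrior()].
#' @return A validated \linkS4class{PriorKnowledge}.
#' @export
readPrior <- function(dir) {
    p <- file.path(dir, .PRIOR_FILES)
    missing <- p[!file.exists(p)]
    if (length(missing))
        stop(sprintf("missing prior file(s): %s",
                     paste(basename(missing), collapse = ", ")))
    lr <- utils::read.csv(p[1], stringsAsFactors = FALSE)
    long <- utils::read.csv(p[2], stringsAsFactors = FALSE)
    se <- utils::read.csv(p[3], stringsAsFactors = FALSE)
    tf <- utils::read.csv(p[4], stringsAsFactors = FALSE)
    pw <- utils::read.csv(p[5], stringsAsFactors = FALSE)
    bad <- which(se$weight <= 0 | se$weight > 1)
    if (length(bad))
        stop(sprintf("signaling_edges.csv row %d: weight outside (0, 1]", bad[1]))
    bad <- which(!tf$mode %in% c(-1, 1))
    if (length(bad))
        stop(sprintf("tf_regulons.csv row %d: mode must be -1 or +1", bad[1]))
    bad <- which(duplicated(tf[, c("tf", "target")]))
    if (length(bad))
        stop(sprintf("tf_regulons.csv row %d: duplicate (tf, target) pair", bad[1]))
    bad <- which(duplicated(pw[, c("pathway", "gene")]))
    if (length(bad))
        stop(sprintf("pathway_weights.csv row %d: duplicate (pathway, gene) pair",
                     bad[1]))
    genes <- sort(unique(c(long$gene, lr$ligand, lr$receptor, se$source,
                           se$dest, tf$target, pw$gene)))
    ligands <- unique(long$ligand)
    rp <- matrix(0, length(ligands), length(genes),
                 dimnames = list(ligands, genes))
    rp[cbind(match(long$ligand, ligands), match(long$gene, genes))] <-
        long$potential
    PriorKnowledge(lrNetwork = lr, regulatoryPotential = rp,
                   signalingEdges = se, tfRegulons = tf, pathwayWeights = pw)
}

#' Write ground truth as JSON
#' @param truth a \linkS4class{GroundTruth}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeTruth <- function(truth, path) {
    obj <- list(planted_lrt = truth@plantedLRT,
                planted_tf_shifts = as.list(truth@plantedTfShifts),
                planted_de_genes = truth@plantedDeGenes,
                sex_genes = truth@sexGenes,
                mediators = truth@mediators)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
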