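#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

.CONDITIONS <- c("case", "control")
.SEXES <- c("F", "M")

#' Annotated single-cell count experiment
#'
#' A \linkS4class{SingleCellExperiment} whose \code{counts} assay holds
#' non-negative integer UMI counts and whose \code{colData} carries the four
#' per-cell annotations the communication pipeline relies on:
#' \code{sample_id}, \code{condition} (\code{"case"}/\code{"control"}),
#' \code{cell_type} and \code{sex} (\code{"F"}/\code{"M"}).
#'
#' @export
setClass("CCCExperiment", contains = "SingleCellExperiment")

setValidity("CCCExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is required")
    cnt <- SummarizedExperiment::assay(object, "counts")
    neg <- if (methods::is(cnt, "sparseMatrix")) any(cnt@x < 0) else any(cnt < 0)
    if (isTRUE(neg))
        msg <- c(msg, "counts must be non-negative")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene ids in rownames")
    cd <- SummarizedExperiment::colData(object)
    need <- c("sample_id", "condition", "cell_type", "sex")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        return(sprintf("colData is missing column(s): %s",
                       paste(miss, collapse = ", ")))
    if (!all(cd$condition %in% .CONDITIONS))
        msg <- c(msg, "condition must be 'case' or 'control'")
    if (!all(cd$sex %in% .SEXES))
        msg <- c(msg, "sex must be 'F' or 'M'")
    if (length(msg)) msg else TRUE
})

#' Construct a CCCExperiment from a count matrix and cell metadata
#'
#' @param counts genes x cells matrix (base or \pkg{Matrix} sparse) of
#'   non-negative integers, with gene ids as rownames.
#' @param cellMeta data.frame with one row per cell and columns
#'   \code{sample_id}, \code{condition}, \code{cell_type}, \code{sex}
#'   (optionally \code{barcode} used for colnames).
#' @return A \linkS4class{CCCExperiment}.
#' @examples
#' m <- matrix(rpois(20, 2), 4, 5, dimnames = list(paste0("G", 1:4), NULL))
#' meta <- data.frame(sample_id = "S1", condition = "case",
#'                    cell_type = "astrocytes", sex = "F")[rep(1, 5), ]
#' CCCExperiment(m, meta)
#' @export
CCCExperiment <- function(counts, cellMeta) {
    cellMeta <- as.data.frame(cellMeta)
    if (nrow(cellMeta) != ncol(counts))
        stop("cellMeta must have one row per column of counts")
    if (is.null(rownames(counts)))
        stop("counts must have gene ids as rownames")
    if ("barcode" %in% colnames(cellMeta)) {
        if (anyDuplicated(cellMeta$barcode))
            stop("duplicate cell barcodes")
        colnames(counts) <- cellMeta$barcode
    } else if (is.null(colnames(counts))) {
        colnames(counts) <- sprintf("cell%06d", seq_len(ncol(counts)))
        cellMeta$barcode <- colnames(counts)
    }
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(cellMeta, row.names = colnames(counts)))
    new("CCCExperiment", sce)
}

#' Prior knowledge bundle for communication inference
#'
#' Holds the five prior tables the pipeline consumes: a ligand-receptor
#' interaction network, a ligand x gene regulatory-potential matrix, a weighted
#' directed signaling edge list, signed transcription-factor regulons, and
#' pathway gene-weight signatures with responsiveness ranks.
#'
#' @slot lrNetwork data.frame(ligand, receptor).
#' @slot regulatoryPotential non-negative matrix, ligands x genes.
#' @slot signalingEdges data.frame(source, dest, weight), weight in (0, 1].
#' @slot tfRegulons data.frame(tf, target, mode), mode in {-1, +1}.
#' @slot pathwayWeights data.frame(pathway, gene, weight, p_rank).
#' @export
setClass("PriorKnowledge",
    representation(lrNetwork = "data.frame",
                   regulatoryPotential = "matrix",
                   signalingEdges = "data.frame",
                   tfRegulons = "data.frame",
                   pathwayWeights = "data.frame"))

setValidity("PriorKnowledge", function(object) {
    msg <- character()
    lr <- object@lrNetwork
    if (!all(c("ligand", "receptor") %in% colnames(lr)))
        msg <- c(msg, "lrNetwork needs columns ligand, receptor")
    rp <- object@regulatoryPotential
    if (length(rp)) {
        if (any(rp < 0))
            msg <- c(msg, "regulatoryPotential must be non-negative")
        if (any(rowSums(rp > 0) < 1))
            msg <- c(msg, "every ligand row of regulatoryPotential needs >= 1 positive entry")
        if (is.null(rownames(rp)) || is.null(colnames(rp)))
            msg <- c(msg, "regulatoryPotential needs ligand rownames and gene colnames")
    }
    se <- object@signalingEdges
    if (nrow(se)) {
        if (!all(c("source", "dest", "weight") %in% colnames(se)))
            msg <- c(msg, "signalingEdges needs columns source, dest, weight")
        else if (any(se$weight <= 0 | se$weight > 1))
            msg <- c(msg, "signaling edge weights must lie in (0, 1]")
    }
    tf <- object@tfRegulons
    if (nrow(tf)) {
        if (!all(c("tf", "target", "mode") %in% colnames(tf)))
            msg <- c(msg, "tfRegulons needs columns tf, target, mode")
        else {
            if (!all(tf$mode %in% c(-1, 1)))
                msg <- c(msg, "regulon mode must be -1 or +1")
            if (anyDuplicated(tf[, c("tf", "target")]))
                msg <- c(msg, "duplicate (tf, target) pair in tfRegulons")
        }
    }
    pw <- object@pathwayWeights
    if (nrow(pw)) {
        if (!all(c("pathway", "gene", "weight", "p_rank") %in% colnames(pw)))
            msg <- c(msg, "pathwayWeights needs columns pathway, gene, weight, p_rank")
        else {
            if (anyDuplicated(pw[, c("pathway", "gene")]))
                msg <- c(msg, "duplicate (pathway, gene) pair in pathwayWeights")
            if (any(pw$p_rank <= 0))
                msg <- c(msg, "p_rank must be positive")
        }
    }
    if (length(msg)) msg else TRUE
})

#' @param lrNetwork,regulatoryPotential,signalingEdges,tfRegulons,pathwayWeights
#'   see the class slots.
#' @return A \linkS4class{PriorKnowledge}.
#' @rdname PriorKnowledge-class
#' @export
PriorKnowledge <- function(lrNetwork, regulatoryPotential, signalingEdges,
                           tfRegulons, pathwayWeights) {
    new("PriorKnowledge",
        lrNetwork = as.data.frame(lrNetwork),
        regulatoryPotential = as.matrix(regulatoryPotential),
        signalingEdges = as.data.frame(signalingEdges),
        tfRegulons = as.data.frame(tfRegulons),
        pathwayWeights = as.data.frame(pathwayWeights))
}

setMethod("show", "PriorKnowledge", function(object) {
    cat("PriorKnowledge\n",
        sprintf("  LR network:           %d pairs (%d ligands, %d receptors)\n",
                nrow(object@lrNetwork),
                length(unique(object@lrNetwork$ligand)),
                length(unique(object@lrNetwork$receptor))),
        sprintf("  regulatory potential: %d ligands x %d genes\n",
                nrow(object@regulatoryPotential), ncol(object@regulatoryPotential)),
        sprintf("  signaling edges:      %d\n", nrow(object@signalingEdges)),
        sprintf("  TF regulons:          %d TFs, %d edges\n",
                length(unique(object@tfRegulons$tf)), nrow(object@tfRegulons)),
        sprintf("  pathways:             %d\n",
                length(unique(object@pathwayWeights$pathway))), sep = "")
})

#' Planted ground truth of a synthetic study
#'
#' Records everything the generator planted so downstream recovery can be
#' scored: the ligand-receptor-target triples with their sender, receiver and
#' direction; the signed activity shifts of the planted transcription factors;
#' and the per-cell-type differential-expression effects implied by both.
#'
#' @slot plantedLRT data.frame(sender, receiver, ligand, receptor, target,
#'   direction) with direction in \code{up_in_case}/\code{up_in_control}.
#' @slot plantedTfShifts named numeric, TF -> signed log2 shift of its targets.
#' @slot plantedDeGenes data.frame(cell_type, gene, log2fc).
#' @slot sexGenes character, genes carrying the sex effect.
#' @slot baseLogMean named numeric, per-gene baseline log2 mean.
#' @slot mediators data.frame(ligand, receptor, mediator) planted signaling
#'   relays.
#' @export
setClass("GroundTruth",
    representation(plantedLRT = "data.frame",
                   plantedTfShifts = "numeric",
                   plantedDeGenes = "data.frame",
                   sexGenes = "character",
                   baseLogMean = "numeric",
                   mediators = "data.frame"))

setValidity("GroundTruth", function(object) {
    msg <- character()
    p <- object@plantedLRT
    if (nrow(p) && !all(p$direction %in% c("up_in_case", "up_in_control")))
        msg <- c(msg, "direction must be up_in_case or up_in_control")
    universe <- names(object@baseLogMean)
    if (length(universe) && nrow(p)) {
        used <- unique(c(p$ligand, p$receptor, p$target))
        if (!all(used %in% universe))
            msg <- c(msg, "planted gene absent from gene universe")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth\n",
        sprintf("  planted LRT triples: %d (%d LR pairs)\n",
                nrow(object@plantedLRT),
                nrow(unique(object@plantedLRT[, c("ligand", "receptor")]))),
        sprintf("  planted TF shifts:   %d\n", length(object@plantedTfShifts)),
        sprintf("  sex-effect genes:    %d\n", length(object@sexGenes)),
        sprintf("  gene universe:       %d\n", length(object@baseLogMean)),
        sep = "")
})
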