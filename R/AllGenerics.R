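#' @name accessors
#' @title Accessors for PriorKnowledge and GroundTruth slots
#' @param x a \linkS4class{PriorKnowledge} or \linkS4class{GroundTruth}.
#' @return The corresponding table, matrix or vector.
NULL

#' @rdname accessors
#' @export
setGeneric("lrNetwork", function(x) standardGeneric("lrNetwork"))
#' @rdname accessors
#' @export
setMethod("lrNetwork", "PriorKnowledge", function(x) x@lrNetwork)

#' @rdname accessors
#' @export
setGeneric("regulatoryPotential", function(x) standardGeneric("regulatoryPotential"))
#' @rdname accessors
#' @export
setMethod("regulatoryPotential", "PriorKnowledge", function(x) x@regulatoryPotential)

#' @rdname accessors
#' @export
setGeneric("signalingEdges", function(x) standardGeneric("signalingEdges"))
#' @rdname accessors
#' @export
setMethod("signalingEdges", "PriorKnowledge", function(x) x@signalingEdges)

#' @rdname accessors
#' @export
setGeneric("tfRegulons", function(x) standardGeneric("tfRegulons"))
#' @rdname accessors
#' @export
setMethod("tfRegulons", "PriorKnowledge", function(x) x@tfRegulons)

#' @rdname accessors
#' @export
setGeneric("pathwayWeights", function(x) standardGeneric("pathwayWeights"))
#' @rdname accessors
#' @export
setMethod("pathwayWeights", "PriorKnowledge", function(x) x@pathwayWeights)

#' @rdname accessors
#' @export
setGeneric("plantedLRT", function(x) standardGeneric("plantedLRT"))
#' @rdname accessors
#' @export
setMethod("plantedLRT", "GroundTruth", function(x) x@plantedLRT)

#' @rdname accessors
#' @export
setGeneric("plantedTfShifts", function(x) standardGeneric("plantedTfShifts"))
#' @rdname accessors
#' @export
setMethod("plantedTfShifts", "GroundTruth", function(x) x@plantedTfShifts)

#' @rdname accessors
#' @export
setGeneric("plantedDeGenes", function(x) standardGeneric("plantedDeGenes"))
#' @rdname accessors
#' @export
setMethod("plantedDeGenes", "GroundTruth", function(x) x@plantedDeGenes)

#' @rdname accessors
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))
#' @rdname accessors
#' @export
setMethod("geneUniverse", "GroundTruth", function(x) names(x@baseLogMean))
#' @rdname accessors
#' @export
setMethod("geneUniverse", "PriorKnowledge", function(x) colnames(x@regulatoryPotential))
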