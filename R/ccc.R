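#' Differential ligand-receptor candidates between senders and receivers
#'
#' Crosses per-cell-type differential-expression tables with the prior
#' ligand-receptor network: a candidate requires the ligand differentially
#' expressed in a sender and the receptor in a receiver, both passing
#' \code{|log2fc| >= logfcMin} and \code{p <= pMax}, with concordant signs.
#' Concordant positive fold changes define direction \code{up_in_case},
#' concordant negative \code{up_in_control}; mixed signs are excluded.
#'
#' @param de named list of \code{DETable}s, one per cell type.
#' @param prior a \linkS4class{PriorKnowledge}.
#' @param senders,receivers cell-type labels; each must name an entry of
#'   \code{de}.
#' @param logfcMin,pMax differential-expression thresholds (defaults 0.5 and
#'   0.05 on unadjusted p-values).
#' @return data.frame with one row per (sender, receiver, ligand, receptor):
#'   direction plus the ligand/receptor fold changes and p-values.
#' @export
candidateInteractions <- function(de, prior, senders, receivers,
                                  logfcMin = 0.5, pMax = 0.05) {
    missing <- setdiff(c(senders, receivers), names(de))
    if (length(missing))
        stop(sprintf("no DE table for cell type(s): %s",
                     paste(missing, collapse = ", ")))
    lr <- lrNetwork(prior)
    pass <- function(tab) tab[abs(tab$log2fc) >= logfcMin & tab$p <= pMax, ,
                              drop = FALSE]
    out <- list()
    for (s in senders) {
        ligDE <- pass(de[[s]])
        ligDE <- ligDE[ligDE$gene %in% lr$ligand, , drop = FALSE]
        if (!nrow(ligDE)) next
        for (r in receivers) {
            recDE <- pass(de[[r]])
            recDE <- recDE[recDE$gene %in% lr$receptor, , drop = FALSE]
            if (!nrow(recDE)) next
            hit <- merge(merge(lr, ligDE, by.x = "ligand", by.y = "gene"),
                         recDE, by.x = "receptor", by.y = "gene",
                         suffixes = c("_ligand", "_receptor"))
            hit <- hit[sign(hit$log2fc_ligand) == sign(hit$log2fc_receptor), ,
                       drop = FALSE]
            if (!nrow(hit)) next
            out[[paste(s, r)]] <- data.frame(
                sender = s, receiver = r,
                ligand = hit$ligand, receptor = hit$receptor,
                direction = ifelse(hit$log2fc_ligand > 0,
                                   "up_in_case", "up_in_control"),
                ligand_log2fc = hit$log2fc_ligand, ligand_p = hit$p_ligand,
                receptor_log2fc = hit$log2fc_receptor,
                receptor_p = hit$p_receptor)
        }
    }
    res <- if (length(out)) do.call(rbind, out) else
        data.frame(sender = character(), receiver = character(),
                   ligand = character(), receptor = character(),
                   direction = character(), ligand_log2fc = numeric(),
                   ligand_p = numeric(), receptor_log2fc = numeric(),
                   receptor_p = numeric())
    rownames(res) <- NULL
    res[order(res$sender, res$receiver, res$ligand, res$receptor,
              method = "radix"), , drop = FALSE]
}

# top-n genes of a ligand's regulatory-potential row, descending potential,
# ties broken lexicographically by gene id; genes with zero potential are not
# target candidates and never enter the top set
.topPotential <- function(prior, ligand, topN) {
    row <- regulatoryPotential(prior)[ligand, ]
    row <- row[row > 0]
    n <- min(topN, length(row))
    names(row)[.orderDescTies(row, names(row))][seq_len(n)]
}

#' Ligand activity against receiver differential expression
#'
#' For each ligand in the regulatory-potential prior, activity is the Pearson
#' correlation, over the receiver's tested gene universe, between the ligand's
#' regulatory-potential row restricted to its top-\code{topN} genes (zero
#' elsewhere) and the binary indicator of receiver differential expression at
#' the stated thresholds. Constant vectors yield activity 0.
#'
#' @param receiverDe a \code{DETable} for the receiver cell type.
#' @param prior a \linkS4class{PriorKnowledge}.
#' @param logfcMin,pMax thresholds defining the receiver DE gene set.
#' @param topN number of top regulatory-potential targets retained per ligand
#'   (default 250).
#' @return named numeric vector, ligand -> activity.
#' @export
ligandActivity <- function(receiverDe, prior, logfcMin = 0.5, pMax = 0.05,
                           topN = 250L) {
    universe <- receiverDe$gene
    if (!length(universe)) stop("receiver gene universe is empty")
    deSet <- receiverDe$gene[abs(receiverDe$log2fc) >= logfcMin &
                             receiverDe$p <= pMax]
    ind <- as.numeric(universe %in% deSet)
    if (!length(deSet))
        warning("empty receiver DE gene set: all ligand activities are 0")
    rp <- regulatoryPotential(prior)
    vapply(rownames(rp), function(lig) {
        top <- .topPotential(prior, lig, topN)
        v <- ifelse(universe %in% top, rp[lig, ][universe], 0)
        if (stats::sd(v) == 0 || stats::sd(ind) == 0) return(0)
        stats::cor(v, ind)
    }, numeric(1))
}

#' Predicted downstream targets of a ligand-receptor candidate
#'
#' Intersects the ligand's top-\code{topN} regulatory-potential genes with the
#' receiver's differentially expressed genes at the stated thresholds, ordered
#' by potential (descending, ties lexicographic).
#'
#' @param candidate one-row data.frame from [candidateInteractions()].
#' @param receiverDe the receiver's \code{DETable}.
#' @param prior a \linkS4class{PriorKnowledge}.
#' @param topN top regulatory-potential cutoff (default 250; clipped to the
#'   gene universe).
#' @param logfcMin,pMax DE thresholds.
#' @return character vector of target genes (possibly empty).
#' @export
inferTargets <- function(candidate, receiverDe, prior, topN = 250L,
                         logfcMin = 0.5, pMax = 0.05) {
    top <- .topPotential(prior, candidate$ligand, topN)
    deSet <- receiverDe$gene[abs(receiverDe$log2fc) >= logfcMin &
                             receiverDe$p <= pMax]
    top[top %in% deSet]
}

# assemble the full per-cohort LRT table with raw prioritization components
.assembleLRT <- function(candidates, de, prior, pb, topN = 250L,
                         logfcMin = 0.5, pMax = 0.05) {
    if (!nrow(candidates)) return(.emptyLRT())
    cd <- SummarizedExperiment::colData(pb)
    logcpm <- .logCPM(SummarizedExperiment::assay(pb, "counts"))
    counts <- SummarizedExperiment::assay(pb, "counts")

    # per-sample cell-type composition for abundance components
    totCells <- tapply(cd$n_cells, cd$sample_id, sum)
    frac <- function(ct, cond) {
        sel <- cd$cell_type == ct & cd$condition == cond
        if (!any(sel)) return(0)
        mean(cd$n_cells[sel] / as.numeric(totCells[cd$sample_id[sel]]))
    }
    activities <- lapply(stats::setNames(nm = unique(candidates$receiver)),
                         function(r) ligandActivity(de[[r]], prior,
                                                    logfcMin, pMax, topN))
    rows <- list()
    for (k in seq_len(nrow(candidates))) {
        cand <- candidates[k, ]
        rde <- de[[cand$receiver]]
        targets <- inferTargets(cand, rde, prior, topN, logfcMin, pMax)
        if (!length(targets)) next
        dirCond <- if (cand$direction == "up_in_case") "case" else "control"
        sSel <- cd$cell_type == cand$sender
        rSel <- cd$cell_type == cand$receiver
        common <- intersect(cd$sample_id[sSel], cd$sample_id[rSel])
        sCol <- which(sSel)[match(common, cd$sample_id[sSel])]
        rCol <- which(rSel)[match(common, cd$sample_id[rSel])]
        fracExpr <- if (length(common))
            mean(counts[cand$ligand, sCol] > 0 & counts[cand$receptor, rCol] > 0)
        else 0
        sCond <- which(sSel & cd$condition == dirCond)
        rCond <- which(rSel & cd$condition == dirCond)
        tde <- rde[match(targets, rde$gene), ]
        act <- activities[[cand$receiver]]
        rows[[k]] <- data.frame(
            sender = cand$sender, receiver = cand$receiver,
            ligand = cand$ligand, receptor = cand$receptor,
            target = targets, direction = cand$direction,
            ligand_log2fc = cand$ligand_log2fc, ligand_p = cand$ligand_p,
            receptor_log2fc = cand$receptor_log2fc, receptor_p = cand$receptor_p,
            target_log2fc = tde$log2fc, target_p = tde$p,
            ligand_activity = unname(act[cand$ligand]),
            de_ligand = -log10(cand$ligand_p),
            de_receptor = -log10(cand$receptor_p),
            frac_expressed = fracExpr,
            expr_ligand = if (length(sCond))
                mean(logcpm[cand$ligand, sCond]) else 0,
            expr_receptor = if (length(rCond))
                mean(logcpm[cand$receptor, rCond]) else 0,
            ligand_activity_scaled = NA_real_,  # filled across ligands below
            abundance_sender = frac(cand$sender, dirCond),
            abundance_receiver = frac(cand$receiver, dirCond))
    }
    lrt <- if (length(rows)) do.call(rbind, rows) else .emptyLRT()
    if (nrow(lrt)) {
        for (r in unique(lrt$receiver)) {
            act <- activities[[r]]
            scaled <- .minMax(act)
            sel <- lrt$receiver == r
            lrt$ligand_activity_scaled[sel] <- scaled[match(lrt$ligand[sel],
                                                            names(act))]
        }
    }
    rownames(lrt) <- NULL
    lrt
}

.COMPONENTS <- c("de_ligand", "de_receptor", "frac_expressed", "expr_ligand",
                 "expr_receptor", "ligand_activity_scaled",
                 "abundance_sender", "abundance_receiver")

.emptyLRT <- function() {
    cols <- c("sender", "receiver", "ligand", "receptor", "target", "direction")
    out <- as.data.frame(stats::setNames(rep(list(character()), length(cols)), cols))
    num <- c("ligand_log2fc", "ligand_p", "receptor_log2fc", "receptor_p",
             "target_log2fc", "target_p", "ligand_activity", .COMPONENTS,
             "priority_score", "pearson_r", "spearman_r")
    for (n in num) out[[n]] <- numeric()
    out
}

#' Prioritize ligand-receptor-target interactions
#'
#' Min-max scales each of the eight component metrics (differential expression
#' of ligand and receptor, fraction of samples expressing the pair, ligand and
#' receptor expression, scaled ligand activity, sender and receiver abundance)
#' across all candidates of the contrast, then aggregates them as a weighted
#' mean to a \code{priority_score} in [0, 1]. A component constant across
#' candidates contributes 0 to every score. Rows are sorted by descending
#' score with lexicographic (sender, receiver, ligand, receptor, target)
#' tie-breaking.
#'
#' @param lrts LRT table from the candidate/target assembly (see
#'   [runPipeline()]), with the eight component columns populated.
#' @param weights named or ordered non-negative weights for the eight
#'   components; default equal.
#' @return The table with \code{priority_score} filled, sorted.
#' @export
prioritizeInteractions <- function(lrts, weights = NULL) {
    if (!nrow(lrts)) stop("no candidate interactions to prioritize")
    if (is.null(weights)) weights <- rep(1, length(.COMPONENTS))
    if (!is.null(names(weights))) {
        miss <- setdiff(.COMPONENTS, names(weights))
        if (length(miss)) stop(sprintf("missing weight(s): %s",
                                       paste(miss, collapse = ", ")))
        weights <- weights[.COMPONENTS]
    }
    if (length(weights) != length(.COMPONENTS) || any(weights < 0))
        stop("'weights' must be eight non-negative values")
    if (sum(weights) == 0) stop("total weight must be positive")
    scaled <- vapply(.COMPONENTS, function(cmp) .minMax(lrts[[cmp]]),
                     numeric(nrow(lrts)))
    scaled <- matrix(scaled, nrow = nrow(lrts))
    lrts$priority_score <- as.numeric(scaled %*% weights) / sum(weights)
    ord <- order(-lrts$priority_score, lrts$sender, lrts$receiver, lrts$ligand,
                 lrts$receptor, lrts$target, method = "radix")
    out <- lrts[ord, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Dual correlation filter on ligand-receptor-target interactions
#'
#' For each interaction, over the samples common to the sender and receiver
#' pseudobulk units, computes a pair signal and correlates it with the
#' target's receiver pseudobulk expression; rows are retained only when both
#' \code{|Pearson| > rMin} and \code{|Spearman| > rMin} (strict). The default
#' pair signal is the elementwise product of the min-max-scaled ligand
#' (sender) and receptor (receiver) log2(CPM+1) profiles;
#' \code{signal = "separate"} instead requires ligand-target and
#' receptor-target correlations to each pass, reporting the weaker of the two.
#' Interactions with fewer than 4 common samples are dropped with a warning.
#'
#' @param lrts LRT table (typically prioritized).
#' @param pb the cohort's filtered pseudobulk \code{SummarizedExperiment}.
#' @param rMin correlation threshold; default 0.33.
#' @param signal \code{"product"} (default) or \code{"separate"}.
#' @return The filtered table with \code{pearson_r} and \code{spearman_r}
#'   columns populated.
#' @export
correlationFilter <- function(lrts, pb, rMin = 0.33,
                              signal = c("product", "separate")) {
    signal <- match.arg(signal)
    if (!nrow(lrts)) return(lrts)
    cd <- SummarizedExperiment::colData(pb)
    logcpm <- .logCPM(SummarizedExperiment::assay(pb, "counts"))
    pearson <- spearman <- rep(NA_real_, nrow(lrts))
    short <- 0L
    for (k in seq_len(nrow(lrts))) {
        x <- lrts[k, ]
        sSel <- which(cd$cell_type == x$sender)
        rSel <- which(cd$cell_type == x$receiver)
        common <- intersect(cd$sample_id[sSel], cd$sample_id[rSel])
        if (length(common) < 4) { short <- short + 1L; next }
        sCol <- sSel[match(common, cd$sample_id[sSel])]
        rCol <- rSel[match(common, cd$sample_id[rSel])]
        lig <- logcpm[x$ligand, sCol]
        rec <- logcpm[x$receptor, rCol]
        tgt <- logcpm[x$target, rCol]
        if (signal == "product") {
            pair <- .minMax(lig) * .minMax(rec)
            if (stats::sd(pair) == 0 || stats::sd(tgt) == 0) next
            pearson[k] <- stats::cor(pair, tgt)
            spearman[k] <- stats::cor(pair, tgt, method = "spearman")
        } else {
            if (stats::sd(lig) == 0 || stats::sd(rec) == 0 ||
                stats::sd(tgt) == 0) next
            pl <- stats::cor(lig, tgt); pr <- stats::cor(rec, tgt)
            sl <- stats::cor(lig, tgt, method = "spearman")
            sr <- stats::cor(rec, tgt, method = "spearman")
            pearson[k] <- if (abs(pl) < abs(pr)) pl else pr
            spearman[k] <- if (abs(sl) < abs(sr)) sl else sr
        }
    }
    if (short > 0)
        warning(sprintf("%d interaction(s) dropped: < 4 common samples", short))
    lrts$pearson_r <- pearson
    lrts$spearman_r <- spearman
    keep <- !is.na(pearson) & !is.na(spearman) &
        abs(pearson) > rMin & abs(spearman) > rMin
    out <- lrts[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}
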