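#' Combine Wald statistics across cohorts into one matrix
#'
#' Outer-joins the differential-expression tables of one cell type on the
#' gene union across cohorts. Genes missing from a cohort (not tested or not
#' expressed there) get statistic 0; the number of substitutions per column is
#' recorded in the \code{na_substituted} attribute.
#'
#' @param tables named list of \code{DETable}s (name = cohort/contrast label)
#'   for the same cell type.
#' @param cellType label recorded on the result.
#' @return numeric matrix genes x contrasts with attributes \code{cell_type}
#'   and \code{na_substituted}.
#' @export
combineStats <- function(tables, cellType = NA_character_) {
    if (!length(tables)) stop("need at least one DE table")
    if (is.null(names(tables)))
        names(tables) <- sprintf("contrast%d", seq_along(tables))
    for (nm in names(tables))
        if (anyDuplicated(tables[[nm]]$gene))
            stop(sprintf("duplicate gene in table '%s'", nm))
    genes <- sort(Reduce(union, lapply(tables, `[[`, "gene")))
    m <- vapply(tables, function(tab)
        tab$wald_stat[match(genes, tab$gene)], numeric(length(genes)))
    m <- matrix(m, nrow = length(genes),
                dimnames = list(genes, names(tables)))
    nas <- colSums(is.na(m))
    m[is.na(m)] <- 0
    attr(m, "cell_type") <- cellType
    attr(m, "na_substituted") <- nas
    m
}

#' Build a signed regulon (or weighted pathway) design matrix
#'
#' For transcription factors, entries are the signed mode (+1 activation, -1
#' repression) of each (target, TF) pair over the supplied gene universe. For
#' pathways, entries are the signature weights of each pathway's top
#' \code{pathwayTopN} most responsive genes (smallest \code{p_rank}, ties
#' broken lexicographically by gene). Regulators with fewer than
#' \code{minTargets} nonzero entries over the universe are dropped (inclusive
#' threshold).
#'
#' @param prior a \linkS4class{PriorKnowledge}.
#' @param genes ordered gene universe (rows of the result).
#' @param minTargets minimum represented targets per regulator; default 5.
#' @param type \code{"tf"} or \code{"pathway"}.
#' @param pathwayTopN responsiveness cutoff for pathway signatures; default 500.
#' @return numeric matrix genes x regulators.
#' @export
buildRegulonMatrix <- function(prior, genes, minTargets = 5L,
                               type = c("tf", "pathway"), pathwayTopN = 500L) {
    type <- match.arg(type)
    if (type == "tf") {
        reg <- tfRegulons(prior)
        regulators <- sort(unique(reg$tf))
        val <- reg$mode
        tgt <- reg$target
        who <- reg$tf
    } else {
        pw <- pathwayWeights(prior)
        keep <- unlist(lapply(split(seq_len(nrow(pw)), pw$pathway), function(i) {
            ord <- i[order(pw$p_rank[i], pw$gene[i], method = "radix")]
            ord[seq_len(min(pathwayTopN, length(ord)))]
        }), use.names = FALSE)
        pw <- pw[keep, ]
        regulators <- sort(unique(pw$pathway))
        val <- pw$weight
        tgt <- pw$gene
        who <- pw$pathway
    }
    m <- matrix(0, nrow = length(genes), ncol = length(regulators),
                dimnames = list(genes, regulators))
    sel <- tgt %in% genes
    m[cbind(match(tgt[sel], genes), match(who[sel], regulators))] <- val[sel]
    nTargets <- colSums(m != 0)
    m <- m[, nTargets >= minTargets, drop = FALSE]
    attr(m, "n_targets") <- nTargets[nTargets >= minTargets]
    m
}

#' Regulator activity via a jointly fitted multivariate linear model
#'
#' For each contrast column of the statistic matrix, fits one ordinary
#' least-squares regression of the gene-level statistics on an intercept plus
#' all regulator columns simultaneously. The per-regulator t-values
#' (coefficient / standard error) are the activity scores: positive means
#' activator / increased activity, negative repressor / decreased. Two-sided
#' p-values use the t distribution with \code{n_genes - n_regulators - 1}
#' degrees of freedom.
#'
#' @param stats matrix from [combineStats()] (genes x contrasts).
#' @param regulonMatrix matrix from [buildRegulonMatrix()] on the same gene
#'   universe.
#' @return data.frame (class \code{ActivityTable}) with columns
#'   \code{regulator}, \code{contrast}, \code{activity_t}, \code{p},
#'   \code{n_targets}.
#' @export
mlmActivity <- function(stats, regulonMatrix) {
    stats <- as.matrix(stats)
    if (!identical(rownames(stats), rownames(regulonMatrix)))
        regulonMatrix <- regulonMatrix[rownames(stats), , drop = FALSE]
    nGenes <- nrow(stats)
    nReg <- ncol(regulonMatrix)
    if (nGenes <= nReg + 1)
        stop("need more genes than regulators + 1")
    X <- cbind(`(Intercept)` = 1, regulonMatrix)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
        stop(sprintf("rank-deficient regulon design; collinear regulator(s): %s",
                     paste(setdiff(bad, "(Intercept)"), collapse = ", ")))
    }
    df <- nGenes - ncol(X)
    B <- qr.coef(qrX, stats)                      # p x contrasts
    resid <- stats - X %*% B
    s2 <- colSums(resid^2) / df
    unpiv <- order(qrX$pivot)
    XtXinv <- chol2inv(qr.R(qrX))[unpiv, unpiv, drop = FALSE]
    seScale <- sqrt(diag(XtXinv))
    nT <- attr(regulonMatrix, "n_targets")
    if (is.null(nT)) nT <- colSums(regulonMatrix != 0)
    out <- do.call(rbind, lapply(seq_len(ncol(stats)), function(j) {
        se <- seScale * sqrt(s2[j])
        tval <- ifelse(se > 0, B[, j] / se, 0)
        data.frame(regulator = colnames(X), contrast = colnames(stats)[j],
                   activity_t = unname(tval),
                   p = unname(2 * stats::pt(-abs(tval), df)),
                   n_targets = c(NA_integer_, unname(nT)))
    }))
    out <- out[out$regulator != "(Intercept)", , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("ActivityTable", "data.frame")
    out
}

#' Restrict TF activity to signaling mediators
#'
#' Keeps the activity rows of transcription factors that appear as candidate
#' or top mediators in any of the supplied mediator results.
#'
#' @param activity an \code{ActivityTable}.
#' @param mediators list of \code{MediatorResult} (see [topMediators()]).
#' @return The subset table (possibly empty, with a message).
#' @export
mediatorTfActivity <- function(activity, mediators) {
    meds <- unique(unlist(lapply(mediators, function(m)
        c(m$candidate_mediators, m$top_mediators))))
    out <- activity[activity$regulator %in% meds, , drop = FALSE]
    if (!nrow(out))
        message("no signaling mediator is a scored TF; empty activity subset")
    rownames(out) <- NULL
    out
}
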