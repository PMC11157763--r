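.LR_KEY <- c("sender", "receiver", "ligand", "receptor", "direction")
.LRT_KEY <- c("sender", "receiver", "ligand", "receptor", "target", "direction")

.keyString <- function(df, key) do.call(paste, c(df[key], sep = "\r"))

#' Ligand-receptor pairs shared between two cohorts
#'
#' Intersects two cohorts' filtered interaction tables on the key
#' (sender, receiver, ligand, receptor, direction): a pair must replicate with
#' the same sender/receiver cell types and the same direction of change.
#' Each shared key is reported once with both cohorts' priority scores (the
#' maximum across that key's targets within each cohort).
#'
#' @param a,b filtered, prioritized LRT tables of the two cohorts.
#' @return data.frame of shared LR records with \code{score_a}, \code{score_b}.
#' @export
intersectLR <- function(a, b) {
    ka <- .keyString(a, .LR_KEY); kb <- .keyString(b, .LR_KEY)
    shared <- intersect(unique(ka), unique(kb))
    if (!length(shared)) {
        out <- a[0, .LR_KEY, drop = FALSE]
        out$score_a <- out$score_b <- numeric()
        return(out)
    }
    out <- unique(a[ka %in% shared, .LR_KEY, drop = FALSE])
    key <- .keyString(out, .LR_KEY)
    scoreA <- tapply(.scoreOrNA(a), ka, max)
    scoreB <- tapply(.scoreOrNA(b), kb, max)
    out$score_a <- as.numeric(scoreA[key])
    out$score_b <- as.numeric(scoreB[key])
    out <- out[order(out$sender, out$receiver, out$ligand, out$receptor,
                     method = "radix"), , drop = FALSE]
    rownames(out) <- NULL
    out
}

.scoreOrNA <- function(tab)
    if ("priority_score" %in% names(tab)) tab$priority_score else
        rep(NA_real_, nrow(tab))

#' Ligand-receptor-target triples shared between two cohorts
#'
#' Extends [intersectLR()]'s match key with the target gene: the
#' high-confidence set of interactions passing every filter in both cohorts
#' with identical sender, receiver, direction and downstream target.
#'
#' @param a,b filtered, prioritized LRT tables of the two cohorts.
#' @return data.frame of shared LRT records with per-cohort scores.
#' @export
intersectLRT <- function(a, b) {
    ka <- .keyString(a, .LRT_KEY); kb <- .keyString(b, .LRT_KEY)
    shared <- intersect(unique(ka), unique(kb))
    if (!length(shared)) {
        out <- a[0, .LRT_KEY, drop = FALSE]
        out$score_a <- out$score_b <- numeric()
        return(out)
    }
    out <- unique(a[ka %in% shared, .LRT_KEY, drop = FALSE])
    key <- .keyString(out, .LRT_KEY)
    scoreA <- tapply(.scoreOrNA(a), ka, max)
    scoreB <- tapply(.scoreOrNA(b), kb, max)
    out$score_a <- as.numeric(scoreA[key])
    out$score_b <- as.numeric(scoreB[key])
    out <- out[order(out$sender, out$receiver, out$ligand, out$receptor,
                     out$target, method = "radix"), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' High-confidence interaction set across cohorts
#'
#' Shared ligand-receptor pairs and shared ligand-receptor-target triples
#' across two or more cohorts (three-plus cohorts by repeated pairwise
#' intersection; a record must appear in every cohort).
#'
#' @param ... two or more filtered, prioritized LRT tables.
#' @return \code{list(shared_lr, shared_lrt)}.
#' @export
highConfidenceSet <- function(...) {
    tabs <- list(...)
    if (length(tabs) < 2) stop("need at least two cohorts")
    lrtKeys <- lapply(tabs, .keyString, key = .LRT_KEY)
    keep <- Reduce(intersect, lapply(lrtKeys, unique))
    first <- tabs[[1]]
    sharedLRT <- intersectLRT(first[lrtKeys[[1]] %in% keep, , drop = FALSE],
                              tabs[[2]])
    lrKeys <- lapply(tabs, .keyString, key = .LR_KEY)
    keepLR <- Reduce(intersect, lapply(lrKeys, unique))
    sharedLR <- intersectLR(first[lrKeys[[1]] %in% keepLR, , drop = FALSE],
                            tabs[[2]])
    list(shared_lr = sharedLR, shared_lrt = sharedLRT)
}
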