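#' Jaccard similarity of two gene sets
#'
#' \code{|a intersect b| / |a union b|}; 0 means no overlap (cell-type
#' specific), 1 total overlap (shared). Inputs are deduplicated.
#'
#' @param a,b character vectors; at least one must be nonempty.
#' @return numeric in [0, 1].
#' @examples
#' jaccard(c("A", "B"), c("B", "C"))  # 1/3
#' @export
jaccard <- function(a, b) {
    a <- unique(a); b <- unique(b)
    if (!length(a) && !length(b))
        stop("Jaccard similarity is undefined for two empty sets")
    length(intersect(a, b)) / length(union(a, b))
}

.roleGenes <- function(lrts, role) {
    switch(role, ligand = lrts$ligand, receptor = lrts$receptor,
           target = lrts$target)
}

.jiEntry <- function(ga, gb, a, b, stratum = NA_character_) {
    ga <- unique(ga); gb <- unique(gb)
    data.frame(stratum = stratum, group_a = a, group_b = b,
               ji = jaccard(ga, gb), n_a = length(ga), n_b = length(gb),
               n_intersect = length(intersect(ga, gb)))
}

#' Receptor/target similarity between receiver cell types
#'
#' For each sender, the Jaccard similarity between the two (or more) receiver
#' cell types' gene sets of the given role, drawn from that sender's
#' interactions. Ligands are excluded by contract: they are sender-specific,
#' so their overlap between receivers is not evaluated. Senders communicating
#' with fewer than two receivers are omitted with a message.
#'
#' @param lrts a filtered LRT table from one cohort.
#' @param role \code{"receptor"} or \code{"target"}.
#' @return data.frame(stratum = sender, group_a, group_b, ji, n_a, n_b,
#'   n_intersect), symmetric entries reported once per unordered pair.
#' @export
receiverSimilarity <- function(lrts, role = c("receptor", "target")) {
    if (identical(role, "ligand"))
        stop("ligands are sender-specific; receiver overlap is not evaluated")
    role <- match.arg(role)
    out <- list()
    for (s in sort(unique(lrts$sender))) {
        sub <- lrts[lrts$sender == s, , drop = FALSE]
        recs <- sort(unique(sub$receiver))
        if (length(recs) < 2) {
            message(sprintf("receiverSimilarity: sender '%s' reaches one receiver; omitted", s))
            next
        }
        pairs <- utils::combn(recs, 2)
        for (j in seq_len(ncol(pairs))) {
            a <- pairs[1, j]; b <- pairs[2, j]
            out[[length(out) + 1L]] <- .jiEntry(
                .roleGenes(sub[sub$receiver == a, ], role),
                .roleGenes(sub[sub$receiver == b, ], role), a, b, stratum = s)
        }
    }
    res <- if (length(out)) do.call(rbind, out) else
        .jiEntry("x", "x", "a", "b")[0, ]
    attr(res, "role") <- role
    attr(res, "grouping") <- "receiver cell types, stratified by sender"
    res
}

#' Ligand/receptor/target similarity between sender cell types
#'
#' All unordered pairs of sender cell types, with role-gene sets restricted to
#' interactions targeting the given receiver.
#'
#' @param lrts a filtered LRT table from one cohort.
#' @param role \code{"ligand"}, \code{"receptor"} or \code{"target"}.
#' @param receiver receiver cell-type label to condition on.
#' @return data.frame as in [receiverSimilarity()] with sender pairs.
#' @export
senderSimilarity <- function(lrts, role = c("ligand", "receptor", "target"),
                             receiver) {
    role <- match.arg(role)
    if (!receiver %in% lrts$receiver)
        stop(sprintf("unknown receiver '%s'", receiver))
    sub <- lrts[lrts$receiver == receiver, , drop = FALSE]
    senders <- sort(unique(sub$sender))
    out <- list()
    if (length(senders) >= 2) {
        pairs <- utils::combn(senders, 2)
        for (j in seq_len(ncol(pairs))) {
            a <- pairs[1, j]; b <- pairs[2, j]
            out[[length(out) + 1L]] <- .jiEntry(
                .roleGenes(sub[sub$sender == a, ], role),
                .roleGenes(sub[sub$sender == b, ], role), a, b,
                stratum = receiver)
        }
    }
    res <- if (length(out)) do.call(rbind, out) else
        .jiEntry("x", "x", "a", "b")[0, ]
    attr(res, "role") <- role
    attr(res, "grouping") <- sprintf("sender cell types, receiver = %s", receiver)
    res
}
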