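# --- weighted-digraph internals ------------------------------------------
# Edges carry a confidence weight w in (0,1]; path search minimizes the cost
# c = 1 - w + eps, so high-confidence edges are cheap and eps keeps every
# cost strictly positive (Dijkstra validity) while penalizing path length.

.edgeCost <- function(w, eps = 1e-6) 1 - w + eps

# Dijkstra from `source` over an edge list, tracking ALL predecessors that
# achieve the minimal distance so every cost-minimal path can be enumerated.
# Distances accumulate along the path (dist[u] + c), matching a sequential
# per-path sum exactly, so tie detection is consistent with brute-force
# enumeration of the same doubles.
.dijkstra <- function(nodes, edges, source) {
    n <- length(nodes)
    idx <- stats::setNames(seq_len(n), nodes)
    adj <- split(data.frame(to = idx[edges$dest], cost = edges$cost,
                            weight = edges$weight),
                 factor(idx[edges$source], levels = seq_len(n)))
    dist <- rep(Inf, n)
    preds <- vector("list", n)
    dist[idx[source]] <- 0
    done <- rep(FALSE, n)
    repeat {
        cand <- which(!done & is.finite(dist))
        if (!length(cand)) break
        u <- cand[which.min(dist[cand])]
        done[u] <- TRUE
        out <- adj[[u]]
        if (is.null(out) || !nrow(out)) next
        for (j in seq_len(nrow(out))) {
            v <- out$to[j]
            d <- dist[u] + out$cost[j]
            if (d < dist[v]) {
                dist[v] <- d
                preds[[v]] <- u
            } else if (d == dist[v]) {
                preds[[v]] <- unique(c(preds[[v]], u))
            }
        }
    }
    list(dist = stats::setNames(dist, nodes), preds = preds, idx = idx)
}

# enumerate all cost-minimal paths source -> target by predecessor backtrack
.minPaths <- function(dj, nodes, target) {
    t <- dj$idx[target]
    if (!is.finite(dj$dist[t])) return(list())
    walk <- function(v) {
        if (dj$dist[v] == 0 && is.null(dj$preds[[v]])) return(list(v))
        unlist(lapply(dj$preds[[v]],
                      function(u) lapply(walk(u), function(p) c(p, v))),
               recursive = FALSE)
    }
    lapply(walk(t), function(p) nodes[p])
}

# single best path (deterministic: lexicographically smallest predecessor)
.bestPath <- function(dj, nodes, target) {
    t <- dj$idx[target]
    if (!is.finite(dj$dist[t])) return(NULL)
    path <- t
    v <- t
    while (!is.null(dj$preds[[v]])) {
        u <- dj$preds[[v]][order(nodes[dj$preds[[v]]], method = "radix")][1]
        path <- c(u, path)
        v <- u
    }
    nodes[path]
}

.pathMeanWeight <- function(path, edges) {
    if (length(path) < 2) return(0)
    key <- paste(edges$source, edges$dest, sep = "\r")
    w <- edges$weight[match(paste(path[-length(path)], path[-1], sep = "\r"), key)]
    mean(w)
}

#' Build the LRT-specific weighted signaling subnetwork
#'
#' Scores every prior-network gene as a candidate regulator of one
#' ligand-receptor-target interaction — the score rewards being downstream of
#' the ligand and upstream of the target, each contribution being the mean
#' edge weight of the best (minimal-cost) path for that role — and induces the
#' subgraph on the anchors (ligand, receptor, target) plus the
#' \code{topKRegulators} best-scoring regulators (ties lexicographic). A
#' ligand-to-receptor edge is ensured (weight 1 when the prior lacks it).
#' Edge costs are \code{1 - weight + eps}.
#'
#' @param lrt one-row data.frame (or list) with \code{ligand},
#'   \code{receptor}, \code{target}.
#' @param prior a \linkS4class{PriorKnowledge}.
#' @param topKRegulators number of regulators to include; default 2.
#' @param eps positivity guard added to every edge cost; default 1e-6.
#' @return A list of class \code{SignalingGraph}: \code{nodes},
#'   \code{edges} (source, dest, weight, cost), \code{anchors},
#'   \code{regulators}.
#' @export
buildSignalingNetwork <- function(lrt, prior, topKRegulators = 2L, eps = 1e-6) {
    anchors <- c(ligand = lrt$ligand, receptor = lrt$receptor,
                 target = lrt$target)
    se <- signalingEdges(prior)
    if (!any(se$source == anchors[["ligand"]] &
             se$dest == anchors[["receptor"]]))
        se <- rbind(se, data.frame(source = anchors[["ligand"]],
                                   dest = anchors[["receptor"]], weight = 1))
    nodes <- sort(unique(c(se$source, se$dest, anchors)))
    se$cost <- .edgeCost(se$weight, eps)

    fromLig <- .dijkstra(nodes, se, anchors[["ligand"]])
    revEdges <- data.frame(source = se$dest, dest = se$source,
                           weight = se$weight, cost = se$cost)
    toTgt <- .dijkstra(nodes, revEdges, anchors[["target"]])

    cand <- setdiff(nodes, anchors)
    score <- vapply(cand, function(g) {
        s <- 0
        if (is.finite(fromLig$dist[g]))
            s <- s + .pathMeanWeight(.bestPath(fromLig, nodes, g), se)
        if (is.finite(toTgt$dist[g]))
            s <- s + .pathMeanWeight(rev(.bestPath(toTgt, nodes, g)), se)
        s
    }, numeric(1))
    cand <- cand[score > 0]
    score <- score[score > 0]
    regs <- cand[.orderDescTies(score, cand)][seq_len(min(topKRegulators,
                                                          length(cand)))]
    keep <- c(unname(anchors), regs)
    sub <- se[se$source %in% keep & se$dest %in% keep, , drop = FALSE]
    rownames(sub) <- NULL
    structure(list(nodes = sort(unique(c(keep, sub$source, sub$dest))),
                   edges = sub, anchors = anchors, regulators = regs),
              class = "SignalingGraph")
}

#' Candidate signaling mediators of a network
#'
#' All nodes with an edge outgoing from the receptor, excluding the ligand
#' and the target themselves.
#'
#' @param g a \code{SignalingGraph}.
#' @return sorted character vector (possibly empty).
#' @export
candidateMediators <- function(g) {
    if (!g$anchors[["receptor"]] %in% g$nodes)
        stop("receptor node absent from the signaling graph")
    out <- g$edges$dest[g$edges$source == g$anchors[["receptor"]]]
    sort(setdiff(unique(out), c(g$anchors[["ligand"]], g$anchors[["target"]])))
}

#' Top signaling mediators by minimal-cost receptor-to-target paths
#'
#' Runs Dijkstra's algorithm from the receptor and enumerates every
#' cost-minimal path to the target. The top mediators are the union of the
#' interior nodes of all minimal paths, in lexicographic order. The
#' interaction is flagged \emph{direct} when the single receptor-to-target
#' edge is the unique minimal path; an unreachable target yields an empty
#' result with \code{reachable = FALSE}.
#'
#' @param g a \code{SignalingGraph}.
#' @return list of class \code{MediatorResult}: \code{ligand},
#'   \code{receptor}, \code{target}, \code{candidate_mediators},
#'   \code{top_mediators}, \code{is_direct}, \code{path_cost},
#'   \code{reachable}.
#' @export
topMediators <- function(g) {
    rec <- g$anchors[["receptor"]]; tgt <- g$anchors[["target"]]
    res <- list(ligand = g$anchors[["ligand"]], receptor = rec, target = tgt,
                candidate_mediators = candidateMediators(g),
                top_mediators = character(), is_direct = FALSE,
                path_cost = Inf, reachable = FALSE)
    class(res) <- "MediatorResult"
    dj <- .dijkstra(g$nodes, g$edges, rec)
    if (!is.finite(dj$dist[tgt])) return(res)
    paths <- .minPaths(dj, g$nodes, tgt)
    stopifnot(all(vapply(paths, function(p) p[1] == rec, logical(1))))
    res$reachable <- TRUE
    res$path_cost <- unname(dj$dist[tgt])
    interior <- sort(unique(unlist(lapply(paths, function(p)
        p[-c(1, length(p))]))))
    res$top_mediators <- interior
    res$is_direct <- length(paths) == 1 && length(paths[[1]]) == 2
    res
}

#' Mediator results for a set of high-confidence interactions
#'
#' Convenience wrapper running [buildSignalingNetwork()] and [topMediators()]
#' for each row of a shared-LRT table.
#'
#' @param sharedLRT data.frame with ligand/receptor/target columns.
#' @param prior a \linkS4class{PriorKnowledge}.
#' @param topKRegulators passed through; default 2.
#' @return list of \code{MediatorResult}, one per row.
#' @export
mediatorsForLRTs <- function(sharedLRT, prior, topKRegulators = 2L) {
    lapply(seq_len(nrow(sharedLRT)), function(k) {
        g <- buildSignalingNetwork(sharedLRT[k, ], prior, topKRegulators)
        topMediators(g)
    })
}
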