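# Independent oracles and small fixtures used across the suite.

suppressPackageStartupMessages({
    library(SummarizedExperiment)
})

# small, fast simulation configuration for unit tests
tinyConfig <- function(...) {
    simConfig(nGenes = 400, nTfs = 10, nPlantedTfs = 2, nPlantedLR = 4,
              nSamplesCase = 4, nSamplesControl = 4,
              cellTypes = c(astrocytes = "sender", microglia = "sender",
                            excitatory = "receiver", inhibitory = "receiver"),
              cellsPerSamplePerType = c(8, 12), seed = 42, ...)
}

lrtKey <- function(d)
    paste(d$sender, d$receiver, d$ligand, d$receptor, d$target, d$direction)

# brute-force Jaccard: element-by-element membership counting, no set ops
jaccardOracle <- function(a, b) {
    a <- a[!duplicated(a)]; b <- b[!duplicated(b)]
    everything <- c(a, b)
    everything <- everything[!duplicated(everything)]
    inter <- 0L; uni <- 0L
    for (x in everything) {
        ina <- any(a == x); inb <- any(b == x)
        if (ina && inb) inter <- inter + 1L
        if (ina || inb) uni <- uni + 1L
    }
    inter / uni
}

# exhaustive simple-path enumeration oracle for minimal-cost paths
allSimplePaths <- function(edges, from, to) {
    paths <- list()
    walk <- function(node, visited, acc) {
        if (node == to) { paths[[length(paths) + 1L]] <<- acc; return() }
        nxt <- edges$dest[edges$source == node]
        for (v in nxt) if (!v %in% visited)
            walk(v, c(visited, v), c(acc, v))
    }
    walk(from, from, from)
    paths
}

pathCost <- function(path, edges) {
    if (length(path) < 2) return(0)
    tot <- 0
    for (i in seq_len(length(path) - 1))
        tot <- tot + edges$cost[edges$source == path[i] &
                                edges$dest == path[i + 1]][1]
    tot
}

# oracle equivalent of topMediators(): enumerate, minimize, take interior union
mediatorOracle <- function(edges, from, to) {
    paths <- allSimplePaths(edges, from, to)
    if (!length(paths))
        return(list(reachable = FALSE, cost = Inf, interior = character(),
                    direct = FALSE))
    costs <- vapply(paths, pathCost, numeric(1), edges = edges)
    best <- paths[costs == min(costs)]
    interior <- sort(unique(unlist(lapply(best, function(p)
        p[-c(1, length(p))]))))
    list(reachable = TRUE, cost = min(costs), interior = interior,
         direct = length(best) == 1 && length(best[[1]]) == 2)
}

randomDigraph <- function(nNodes, p = 0.35) {
    nodes <- LETTERS[seq_len(nNodes)]
    grid <- expand.grid(source = nodes, dest = nodes,
                        stringsAsFactors = FALSE)
    grid <- grid[grid$source != grid$dest, ]
    grid <- grid[runif(nrow(grid)) < p, ]
    grid$weight <- runif(nrow(grid), 0.01, 1)
    grid$cost <- 1 - grid$weight + 1e-6
    rownames(grid) <- NULL
    grid
}

asSignalingGraph <- function(edges, receptor, target) {
    nodes <- sort(unique(c(edges$source, edges$dest, receptor, target)))
    structure(list(nodes = nodes, edges = edges,
                   anchors = c(ligand = receptor, receptor = receptor,
                               target = target),
                   regulators = character()),
              class = "SignalingGraph")
}

# textbook normal-equations OLS: coefficients, standard errors, t-statistics
olsOracle <- function(X, y) {
    XtX <- t(X) %*% X
    XtXinv <- solve(XtX)
    beta <- XtXinv %*% t(X) %*% y
    res <- y - X %*% beta
    df <- nrow(X) - ncol(X)
    s2 <- sum(res^2) / df
    se <- unname(sqrt(s2 * diag(XtXinv)))
    beta <- unname(drop(beta))
    list(beta = beta, se = se, t = beta / se, df = df)
}

# assemble a pseudobulk SummarizedExperiment directly from a count matrix
makePseudobulk <- function(counts, sampleId, cellType, condition, sex,
                           nCells = rep(10L, length(sampleId))) {
    colnames(counts) <- paste(sampleId, cellType, sep = "|")
    SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(sample_id = sampleId,
                                       cell_type = cellType,
                                       condition = condition, sex = sex,
                                       n_cells = as.integer(nCells),
                                       row.names = colnames(counts)))
}
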