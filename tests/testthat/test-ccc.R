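makeDE <- function(genes, log2fc, p) {
    tab <- data.frame(gene = genes, log2fc = log2fc, wald_stat = log2fc,
                      p = p, p_adj = p)
    class(tab) <- c("DETable", "data.frame")
    tab
}

smallPrior <- function(lr, genes, potential = NULL) {
    if (is.null(potential)) {
        potential <- matrix(1, nrow = length(unique(lr$ligand)),
                            ncol = length(genes),
                            dimnames = list(unique(lr$ligand), genes))
    }
    PriorKnowledge(lrNetwork = lr, regulatoryPotential = potential,
                   signalingEdges = data.frame(source = character(),
                                               dest = character(),
                                               weight = numeric()),
                   tfRegulons = data.frame(tf = character(),
                                           target = character(),
                                           mode = numeric()),
                   pathwayWeights = data.frame(pathway = character(),
                                               gene = character(),
                                               weight = numeric(),
                                               p_rank = numeric()))
}

test_that("candidate detection enforces thresholds and sign concordance", {
    genes <- c("L1", "L2", "L3", "R1", "R2", "R3")
    lr <- data.frame(ligand = c("L1", "L2", "L3"),
                     receptor = c("R1", "R2", "R3"))
    prior <- smallPrior(lr, genes)
    de <- list(
        glia = makeDE(c("L1", "L2", "L3"), c(0.6, 0.6, 0.4), c(0.01, 0.01, 0.001)),
        neurons = makeDE(c("R1", "R2", "R3"), c(0.8, -0.6, 0.9), c(0.02, 0.02, 0.01)))
    out <- candidateInteractions(de, prior, "glia", "neurons")
    # L1-R1 concordant up; L2-R2 discordant; L3 below the fold threshold
    expect_equal(out$ligand, "L1")
    expect_equal(out$direction, "up_in_case")
    expect_equal(out$ligand_log2fc, 0.6)

    # concordant negative pair is up_in_control
    de2 <- list(glia = makeDE("L1", -0.7, 0.01),
                neurons = makeDE("R1", -0.9, 0.03))
    out2 <- candidateInteractions(de2, prior, "glia", "neurons")
    expect_equal(out2$direction, "up_in_control")
    expect_error(candidateInteractions(de, prior, "glia", "absent"), "absent")
})

test_that("ligand activity equals a hand-computed Pearson correlation", {
    genes <- sprintf("g%02d", 1:10)
    pot <- matrix(0, 2, 10, dimnames = list(c("L1", "L2"), genes))
    pot["L1", 1:5] <- c(0.9, 0.8, 0.7, 0.6, 0.5)
    pot["L2", 6:9] <- c(0.9, 0.85, 0.8, 0.75)
    prior <- smallPrior(data.frame(ligand = c("L1", "L2"),
                                   receptor = c("R1", "R2")), genes, pot)
    de <- makeDE(genes, c(2, 2, 0, 0, 0, 0, 0, 0, 0, 2),
                 c(0.01, 0.01, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9, 0.01))
    act <- ligandActivity(de, prior, topN = 3)
    ind <- as.numeric(abs(de$log2fc) >= 0.5 & de$p <= 0.05)
    v1 <- ifelse(genes %in% c("g01", "g02", "g03"), pot["L1", ], 0)
    expect_equal(unname(act["L1"]), cor(v1, ind), tolerance = 1e-12)
    # a ligand whose top targets avoid the DE set scores non-positive
    expect_lte(act["L2"], 0)
    # perfect overlap of support and DE set is the maximum across ligands
    de2 <- makeDE(genes, c(2, 2, 2, 0, 0, 0, 0, 0, 0, 0),
                  c(rep(0.01, 3), rep(0.9, 7)))
    act2 <- ligandActivity(de2, prior, topN = 3)
    expect_equal(names(which.max(act2)), "L1")
    expect_warning(
        ligandActivity(makeDE(genes, rep(0, 10), rep(1, 10)), prior),
        "empty")
})

test_that("target inference intersects top potential with DE genes", {
    genes <- sprintf("g%02d", 1:10)
    pot <- matrix(0, 1, 10, dimnames = list("L1", genes))
    pot["L1", 1:6] <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
    prior <- smallPrior(data.frame(ligand = "L1", receptor = "R1"),
                        genes, pot)
    de <- makeDE(genes, rep(c(2, 0), c(4, 6)),
                 rep(c(0.01, 0.9), c(4, 6)))
    cand <- data.frame(ligand = "L1", receptor = "R1")
    expect_equal(inferTargets(cand, de, prior, topN = 3), c("g01", "g02", "g03"))
    # topN larger than the positive support clips to the support
    expect_equal(inferTargets(cand, de, prior, topN = 250),
                 c("g01", "g02", "g03", "g04"))
    # tie at the rank boundary is broken lexicographically
    pot2 <- pot; pot2["L1", ] <- 0
    pot2["L1", c("g05", "g03", "g02")] <- c(0.9, 0.5, 0.5)
    prior2 <- smallPrior(data.frame(ligand = "L1", receptor = "R1"),
                         genes, pot2)
    expect_equal(inferTargets(cand, de, prior2, topN = 2), c("g02"))
    # g05 ranks 1 (but is not DE? g05 not DE: de has g01..g04 DE) ->
    # top-2 = {g05, g02} (g02 beats g03 lexicographically), intersect DE = g02
})

test_that("prioritization min-max scales, aggregates and orders stably", {
    lrt <- data.frame(sender = "s", receiver = "r",
                      ligand = c("L1", "L2", "L3"),
                      receptor = "R", target = c("t1", "t2", "t3"),
                      direction = "up_in_case",
                      de_ligand = c(2, 4, 6), de_receptor = c(1, 1, 1),
                      frac_expressed = c(0, 0.5, 1),
                      expr_ligand = c(5, 3, 1), expr_receptor = c(2, 2, 2),
                      ligand_activity_scaled = c(0, 1, 0.5),
                      abundance_sender = c(0.1, 0.1, 0.1),
                      abundance_receiver = c(0.2, 0.2, 0.2))
    out <- prioritizeInteractions(lrt)
    # hand-computed: scaled components per candidate / 8 (constant cols -> 0)
    hand <- c(L1 = (0 + 0 + 1 + 0) / 8, L2 = (0.5 + 0.5 + 0.5 + 1) / 8,
              L3 = (1 + 1 + 0 + 0.5) / 8)
    expect_equal(out$priority_score[match(c("L1", "L2", "L3"), out$ligand)],
                 unname(hand), tolerance = 1e-12)
    expect_true(all(out$priority_score >= 0 & out$priority_score <= 1))
    expect_equal(out$ligand[1], "L2")

    # invariance to a strictly increasing affine transform of one component
    lrt2 <- lrt
    lrt2$de_ligand <- 10 + 3 * lrt2$de_ligand
    expect_equal(prioritizeInteractions(lrt2)$priority_score,
                 out$priority_score, tolerance = 1e-12)
    expect_error(prioritizeInteractions(lrt, weights = rep(0, 8)), "weight")
})

test_that("the correlation filter requires both coefficients to pass", {
    samples <- sprintf("S%d", 1:8)
    lig <- c(1, 2, 3, 4, 5, 6, 7, 8) * 10L
    tgtPerfect <- lig * 3L
    counts <- rbind(L = lig, R = lig, Tp = tgtPerfect,
                    flat = rep(1000L, 8))
    pb <- makePseudobulk(cbind(counts, counts), rep(samples, 2),
                         rep(c("glia", "neurons"), each = 8),
                         rep(rep(c("case", "control"), each = 4), 2),
                         rep("F", 16))
    base <- data.frame(sender = "glia", receiver = "neurons", ligand = "L",
                       receptor = "R", target = "Tp",
                       direction = "up_in_case")
    kept <- correlationFilter(base, pb)
    expect_equal(nrow(kept), 1)
    expect_gt(kept$pearson_r, 0.9)
    expect_gt(kept$spearman_r, 0.9)

    # Pearson dominated by one outlier while ranks are scrambled: the
    # Spearman threshold must reject even though Pearson passes
    set.seed(8)
    scr <- c(5, 3, 8, 1, 7, 2, 6, 200) * 10L
    counts2 <- rbind(L = lig, R = lig, Ts = scr, flat = rep(1000L, 8))
    pb2 <- makePseudobulk(cbind(counts2, counts2), rep(samples, 2),
                          rep(c("glia", "neurons"), each = 8),
                          rep(rep(c("case", "control"), each = 4), 2),
                          rep("F", 16))
    base2 <- base; base2$target <- "Ts"
    both <- correlationFilter(rbind(base, base2)[2, ], pb2)
    expect_equal(nrow(both), 0)

    # fewer than 4 shared samples: dropped with a warning
    pb3 <- pb[, c(1:3, 9:11)]
    expect_warning(out3 <- correlationFilter(base, pb3), "4 common samples")
    expect_equal(nrow(out3), 0)
})

test_that("null targets rarely survive the dual correlation filter", {
    # white-noise targets: the kept fraction matches a direct Monte-Carlo
    # estimate of P(|pearson| > 0.33 and |spearman| > 0.33) under the null
    set.seed(10)
    n <- 8
    pair <- runif(n)
    nSim <- 1000
    keep <- logical(nSim)
    for (i in seq_len(nSim)) {
        tgt <- rnorm(n)
        keep[i] <- abs(cor(pair, tgt)) > 0.33 &&
            abs(cor(pair, tgt, method = "spearman")) > 0.33
    }
    pNull <- mean(keep)
    expect_lt(pNull, 0.35)

    lig <- as.integer(round(pair * 1000) + 10)
    tgts <- matrix(rpois(200 * n, 50), nrow = 200,
                   dimnames = list(sprintf("t%03d", 1:200), NULL))
    counts <- rbind(L = lig, R = lig, tgts, flat = rep(5000L, n))
    # both cell types see the same matrix; ligand/receptor read from glia units
    pb <- makePseudobulk(cbind(counts, counts), rep(sprintf("S%d", 1:n), 2),
                         rep(c("glia", "neurons"), each = n),
                         rep(rep(c("case", "control"), each = n / 2), 2),
                         rep("F", 2 * n))
    lrts <- data.frame(sender = "glia", receiver = "neurons", ligand = "L",
                       receptor = "R", target = rownames(tgts),
                       direction = "up_in_case")
    kept <- correlationFilter(lrts, pb)
    expect_lt(nrow(kept) / nrow(lrts), pNull + 0.15)
    if (nrow(kept))
        expect_true(all(abs(kept$pearson_r) > 0.33 &
                        abs(kept$spearman_r) > 0.33))
})
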