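deTab <- function(genes, stat) {
    data.frame(gene = genes, log2fc = stat, wald_stat = stat,
               p = 0.5, p_adj = 0.5)
}

regPrior <- function(tf, pathway = NULL) {
    if (is.null(pathway))
        pathway <- data.frame(pathway = character(), gene = character(),
                              weight = numeric(), p_rank = numeric())
    PriorKnowledge(
        lrNetwork = data.frame(ligand = "L", receptor = "R"),
        regulatoryPotential = matrix(1, 1, 1, dimnames = list("L", "g1")),
        signalingEdges = data.frame(source = character(), dest = character(),
                                    weight = numeric()),
        tfRegulons = tf, pathwayWeights = pathway)
}

test_that("cross-cohort statistic assembly replaces missing genes with zero", {
    a <- deTab(c("g1", "g2", "g3"), c(2.4, -1, 0.5))
    b <- deTab(c("g2", "g4"), c(3, 1.2))
    m <- combineStats(list(A = a, B = b), "inh")
    expect_equal(rownames(m), c("g1", "g2", "g3", "g4"))
    expect_equal(unname(m["g1", ]), c(2.4, 0))       # present in A only
    expect_equal(unname(m["g4", ]), c(0, 1.2))
    expect_equal(unname(attr(m, "na_substituted")), c(1, 2))
    # substitution count is |union| - |each table's genes|
    expect_equal(sum(attr(m, "na_substituted")),
                 2 * length(union(a$gene, b$gene)) - nrow(a) - nrow(b))
    ident <- combineStats(list(A = a, B = a))
    expect_equal(unname(ident[, 1]), unname(ident[, 2]))
    dup <- rbind(a, a[1, ])
    expect_error(combineStats(list(A = dup)), "duplicate gene")
})

test_that("regulon matrices enforce the inclusive minimum-target rule", {
    genes <- sprintf("g%02d", 1:20)
    tf <- rbind(data.frame(tf = "TF5", target = genes[1:5],
                           mode = c(1, 1, -1, 1, -1)),
                data.frame(tf = "TF4", target = genes[6:9], mode = 1),
                data.frame(tf = "TFX", target = c(genes[10:13], "absent"),
                           mode = 1))
    m <- buildRegulonMatrix(regPrior(tf), genes, minTargets = 5)
    expect_equal(colnames(m), "TF5")                 # 4 present targets excluded
    expect_equal(unname(m[genes[1:5], "TF5"]), c(1, 1, -1, 1, -1))
    m4 <- buildRegulonMatrix(regPrior(tf), genes, minTargets = 4)
    expect_setequal(colnames(m4), c("TF5", "TF4", "TFX"))
})

test_that("pathway signatures keep the top responsive genes by p-rank", {
    genes <- sprintf("g%03d", 1:600)
    pw <- data.frame(pathway = "PW1", gene = genes,
                     weight = seq(-1, 1, length.out = 600),
                     p_rank = c(rep(1, 2), 3:600))   # tie at the top
    m <- buildRegulonMatrix(regPrior(tf = data.frame(tf = character(),
                                                     target = character(),
                                                     mode = numeric()),
                                     pathway = pw),
                            genes, minTargets = 5, type = "pathway",
                            pathwayTopN = 500)
    expect_equal(sum(m != 0), 500)
    # boundary tie at the cutoff rank resolves lexicographically
    pw2 <- data.frame(pathway = "PW1", gene = c("gB", "gA", "gC"),
                      weight = c(0.5, 0.4, 0.3), p_rank = c(1, 2, 2))
    m2 <- buildRegulonMatrix(regPrior(tf = data.frame(tf = character(),
                                                      target = character(),
                                                      mode = numeric()),
                                      pathway = pw2),
                             c("gA", "gB", "gC"), minTargets = 2,
                             type = "pathway", pathwayTopN = 2)
    expect_equal(sort(rownames(m2)[m2[, 1] != 0]), c("gA", "gB"))
})

test_that("joint-model t-values match the normal-equation oracle", {
    set.seed(16)
    genes <- sprintf("g%02d", 1:10)
    R <- matrix(c(1, 1, -1, 0, 0, 1, 0, -1, 1, 0,
                  0, 1, 0, 1, -1, 0, 1, 0, -1, 1), ncol = 2,
                dimnames = list(genes, c("TF1", "TF2")))
    y <- rnorm(10)
    stats <- matrix(y, ncol = 1, dimnames = list(genes, "c1"))
    act <- mlmActivity(stats, R)
    o <- olsOracle(cbind(1, R), y)
    expect_equal(act$activity_t[act$regulator == "TF1"], o$t[2],
                 tolerance = 1e-8)
    expect_equal(act$activity_t[act$regulator == "TF2"], o$t[3],
                 tolerance = 1e-8)
    expect_equal(act$p, 2 * pt(-abs(o$t[2:3]), o$df), tolerance = 1e-10)

    # sign equivariance: negating all modes negates the activity
    actNeg <- mlmActivity(stats, -R)
    expect_equal(actNeg$activity_t, -act$activity_t, tolerance = 1e-10)

    # a null response yields null activity
    act0 <- mlmActivity(matrix(0, 10, 1, dimnames = list(genes, "c1")), R)
    expect_true(all(act0$activity_t == 0))

    # collinear regulators are named in the error
    expect_error(mlmActivity(stats, cbind(R, TF3 = R[, 1])), "TF3|TF1")
    expect_error(mlmActivity(stats[1:3, , drop = FALSE], R[1:3, ]),
                 "more genes")
})

test_that("the joint fit separates correlated regulons where marginal fits cannot", {
    # two regulons sharing most targets with opposite sign; signal placed on
    # TF1 only: the joint model assigns it correctly, the marginal fit of TF2
    # sees a spurious (anti-)signal
    genes <- sprintf("g%02d", 1:12)
    r1 <- c(rep(1, 8), rep(0, 4))
    r2 <- c(rep(-1, 8), 0, 0, 1, 1)
    R <- matrix(c(r1, r2), ncol = 2, dimnames = list(genes, c("TF1", "TF2")))
    y <- 2 * r1 + c(rep(0, 8), 0.1, -0.1, 0.05, -0.05)
    stats <- matrix(y, ncol = 1, dimnames = list(genes, "c1"))
    act <- mlmActivity(stats, R)
    t1 <- act$activity_t[act$regulator == "TF1"]
    t2 <- act$activity_t[act$regulator == "TF2"]
    expect_gt(t1, 0)
    expect_gt(abs(t1), abs(t2))
    marginal2 <- olsOracle(cbind(1, R[, 2]), y)$t[2]
    expect_gt(abs(marginal2), abs(t2))   # marginal misattributes the signal
})

test_that("planted TF shifts are recovered with the correct sign", {
    cfg <- tinyConfig()
    study <- generateStudy(cfg)
    pb <- suppressMessages(filterUnits(pseudobulk(study$cohortA)))
    de <- differentialExpression(pb, "inhibitory")
    stats <- combineStats(list(A = de), "inhibitory")
    R <- buildRegulonMatrix(study$prior, rownames(stats), minTargets = 5)
    act <- mlmActivity(stats, R)
    shifts <- plantedTfShifts(study$truth)
    hit <- act[match(names(shifts), act$regulator), ]
    expect_equal(sign(hit$activity_t), unname(sign(shifts)))
    nullT <- abs(act$activity_t[!act$regulator %in% names(shifts)])
    expect_true(all(abs(hit$activity_t) > quantile(nullT, 0.95)))
})

test_that("upward-shifted pathway signatures yield positive activity", {
    set.seed(17)
    genes <- sprintf("g%03d", 1:200)
    w <- runif(100, 0.5, 2)
    pw <- data.frame(pathway = "PW1", gene = genes[1:100], weight = w,
                     p_rank = 1:100)
    prior <- regPrior(tf = data.frame(tf = character(), target = character(),
                                      mode = numeric()), pathway = pw)
    R <- buildRegulonMatrix(prior, genes, type = "pathway", pathwayTopN = 500)
    y <- rnorm(200, 0, 0.2)
    y[1:100] <- y[1:100] + 1.5 * w      # targets move with their weights
    act <- mlmActivity(matrix(y, ncol = 1, dimnames = list(genes, "c1")), R)
    expect_gt(act$activity_t, 0)
    expect_lt(act$p, 0.01)
})

test_that("mediator subsetting keeps only mediator TFs", {
    act <- data.frame(regulator = c("MYC", "TP53", "JUN"),
                      contrast = "c1", activity_t = 1:3, p = 0.5,
                      n_targets = 10)
    med <- list(list(candidate_mediators = c("MYC", "XX"),
                     top_mediators = "TP53"))
    out <- mediatorTfActivity(act, med)
    expect_setequal(out$regulator, c("MYC", "TP53"))
    expect_message(out2 <- mediatorTfActivity(act,
        list(list(candidate_mediators = "ZZ", top_mediators = character()))),
        "empty")
    expect_equal(nrow(out2), 0)
})
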