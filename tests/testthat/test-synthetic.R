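test_that("prior generation is deterministic and satisfies its contracts", {
    cfg <- tinyConfig()
    pt1 <- generatePrior(cfg)
    pt2 <- generatePrior(cfg)
    expect_identical(lrNetwork(pt1$prior), lrNetwork(pt2$prior))
    expect_identical(regulatoryPotential(pt1$prior),
                     regulatoryPotential(pt2$prior))
    expect_identical(signalingEdges(pt1$prior), signalingEdges(pt2$prior))
    expect_identical(plantedLRT(pt1$truth), plantedLRT(pt2$truth))

    reg <- tfRegulons(pt1$prior)
    expect_equal(nrow(reg), cfg$nTfs * cfg$targetsPerTf)
    expect_equal(length(unique(reg$tf)), cfg$nTfs)
    expect_false(anyDuplicated(reg[, c("tf", "target")]) > 0)

    se <- signalingEdges(pt1$prior)
    expect_true(all(se$weight > 0 & se$weight <= 1))
    expect_true(all(rowSums(regulatoryPotential(pt1$prior) > 0) >= 1))

    # every planted (ligand, receptor) pair is in the LR network
    tr <- plantedLRT(pt1$truth)
    netKey <- paste(lrNetwork(pt1$prior)$ligand, lrNetwork(pt1$prior)$receptor)
    expect_true(all(paste(tr$ligand, tr$receptor) %in% netKey))
    expect_true(all(tr$direction %in% c("up_in_case", "up_in_control")))
    expect_true(all(unique(c(tr$ligand, tr$receptor, tr$target)) %in%
                    geneUniverse(pt1$truth)))
})

test_that("planted targets sit in the top decile of the ligand's potential row", {
    pt <- generatePrior(tinyConfig())
    tr <- plantedLRT(pt$truth)
    rp <- regulatoryPotential(pt$prior)
    for (lig in unique(tr$ligand)) {
        row <- rp[lig, ]
        q90 <- quantile(row[row > 0], 0.9)
        expect_true(all(row[tr$target[tr$ligand == lig]] >= q90))
    }
})

test_that("every planted triple has a receptor-to-target signaling path", {
    pt <- generatePrior(tinyConfig())
    se <- signalingEdges(pt$prior)
    tr <- plantedLRT(pt$truth)
    reach <- function(from, to) {   # BFS, independent of the Dijkstra code
        seen <- from
        frontier <- from
        while (length(frontier)) {
            nxt <- unique(se$dest[se$source %in% frontier])
            frontier <- setdiff(nxt, seen)
            seen <- c(seen, frontier)
            if (to %in% seen) return(TRUE)
        }
        FALSE
    }
    for (k in seq_len(nrow(tr)))
        expect_true(reach(tr$receptor[k], tr$target[k]))
})

test_that("dataset layout is forced by the configuration", {
    cfg <- simConfig(nGenes = 300, nTfs = 8, nPlantedTfs = 2, nPlantedLR = 2,
                     nSamplesCase = 2, nSamplesControl = 2,
                     cellTypes = c(glia = "sender", neurons = "receiver"),
                     cellsPerSamplePerType = c(50, 50), seed = 7)
    pt <- generatePrior(cfg)
    d <- generateDataset(cfg, pt$prior, pt$truth, 1)
    expect_equal(ncol(d), 2 * 4 * 50)   # 2 cell types x 4 samples x 50 cells
    expect_equal(nrow(d), 300)
    cd <- as.data.frame(SummarizedExperiment::colData(d))
    expect_setequal(unique(cd$condition), c("case", "control"))
    # sex is balanced within condition
    tab <- table(cd[!duplicated(cd$sample_id), c("condition", "sex")])
    expect_true(all(tab == 1))

    d2 <- generateDataset(cfg, pt$prior, pt$truth, 1)
    expect_identical(SummarizedExperiment::assay(d, "counts"),
                     SummarizedExperiment::assay(d2, "counts"))
    d3 <- generateDataset(cfg, pt$prior, pt$truth, 2)
    expect_false(identical(SummarizedExperiment::assay(d, "counts"),
                           SummarizedExperiment::assay(d3, "counts")))
})

test_that("a null configuration produces exchangeable case/control counts", {
    cfg <- simConfig(nGenes = 300, nTfs = 8, nPlantedTfs = 2,
                     cellTypes = c(glia = "sender", neurons = "receiver"),
                     cellsPerSamplePerType = c(40, 40),
                     lrEffectLog2fc = 0, tfActivityShift = 0,
                     sexEffectLog2fc = 0, lrtSampleSd = 0, seed = 3)
    pt <- generatePrior(cfg)
    expect_true(all(plantedDeGenes(pt$truth)$log2fc == 0))
    d <- generateDataset(cfg, pt$prior, pt$truth, 5)
    cd <- SummarizedExperiment::colData(d)
    m <- SummarizedExperiment::assay(d, "counts")
    caseMean <- mean(as.matrix(m[, cd$condition == "case"]))
    ctrlMean <- mean(as.matrix(m[, cd$condition == "control"]))
    expect_lt(abs(caseMean - ctrlMean) / ctrlMean, 0.05)
})

test_that("planted ligand fold change is recovered in sender pseudobulk", {
    # Monte-Carlo over replicate cohorts: up_in_case ligand at log2fc = 2
    # should show a case/control pseudobulk mean ratio near 4 in sender cells
    cfg <- simConfig(nGenes = 300, nTfs = 8, nPlantedTfs = 0, nPlantedLR = 2,
                     cellTypes = c(glia = "sender", neurons = "receiver"),
                     cellsPerSamplePerType = c(20, 20), lrtSampleSd = 0,
                     seed = 9)
    pt <- generatePrior(cfg)
    tr <- plantedLRT(pt$truth)
    lig <- tr$ligand[tr$direction == "up_in_case"][1]
    sender <- tr$sender[tr$direction == "up_in_case"][1]
    ratios <- vapply(seq_len(20), function(s) {
        d <- generateDataset(cfg, pt$prior, pt$truth, 1000 + s)
        cd <- SummarizedExperiment::colData(d)
        m <- SummarizedExperiment::assay(d, "counts")
        sel <- cd$cell_type == sender
        mean(m[lig, sel & cd$condition == "case"]) /
            mean(m[lig, sel & cd$condition == "control"])
    }, numeric(1))
    expect_lt(abs(mean(ratios) - 4), 0.6)
})

test_that("two cohorts of a study share truth but differ in noise", {
    cfg <- tinyConfig()
    study <- generateStudy(cfg)
    expect_identical(rownames(study$cohortA), rownames(study$cohortB))
    expect_setequal(
        unique(SummarizedExperiment::colData(study$cohortA)$cell_type),
        unique(SummarizedExperiment::colData(study$cohortB)$cell_type))
    expect_false(identical(
        SummarizedExperiment::assay(study$cohortA, "counts"),
        SummarizedExperiment::assay(study$cohortB, "counts")))
})

test_that("invalid configurations are rejected with the field name", {
    expect_error(simConfig(nGenes = 0), "nGenes")
    expect_error(simConfig(nbDispersion = -1), "nbDispersion")
    expect_error(simConfig(cellTypes = c(a = "sender")), "receiver")
    expect_error(simConfig(nGenes = 100), "nGenes")
    expect_error(simConfig(nPlantedTfs = 60), "nPlantedTfs")
})

test_that("dataset generation rejects truth outside the gene universe", {
    cfg <- tinyConfig()
    pt <- generatePrior(cfg)
    bad <- pt$truth
    bad@plantedDeGenes$gene[1] <- "NOT_A_GENE"
    expect_error(generateDataset(cfg, pt$prior, bad, 1), "NOT_A_GENE")
})
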