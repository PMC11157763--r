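#' Simulation configuration for synthetic two-cohort studies
#'
#' Builds and validates the configuration driving the synthetic-data generator.
#' Defaults emulate a two-cohort postmortem-cortex study design: four glial
#' sender populations (astrocytes, microglia, oligodendrocytes, OPCs) signaling
#' to two neuronal receivers (excitatory, inhibitory), case/control samples,
#' negative-binomial counts, planted ligand-receptor-target effects, planted
#' signed TF-activity shifts and a balanced sex covariate.
#'
#' @param nGenes gene universe size.
#' @param nSamplesCase,nSamplesControl samples per condition per cohort.
#' @param cellTypes named character vector mapping cell-type label to role
#'   (\code{"sender"}, \code{"receiver"} or \code{"other"}).
#' @param cellsPerSamplePerType length-2 integer range of cells drawn per
#'   (sample, cell type).
#' @param nbDispersion negative-binomial size (shape) parameter; smaller means
#'   noisier counts.
#' @param baselineLogMeanRange log2-scale interval for per-gene baseline mean
#'   counts per cell.
#' @param nPlantedLR number of planted ligand-receptor pairs.
#' @param lrEffectLog2fc log2 fold change planted on ligands (sender),
#'   receptors and targets (receiver) in the direction's condition.
#' @param nTargetsPerLigand planted downstream targets per ligand.
#' @param nTfs,nPlantedTfs,targetsPerTf,tfActivityShift TF regulon prior size,
#'   number of TFs given an activity shift, regulon size, and the absolute
#'   log2 shift applied to regulon targets (mode-signed) in case receivers.
#' @param sexEffectLog2fc,sexGeneFraction log2 shift applied to a random gene
#'   subset in male samples, and the fraction of genes affected.
#' @param batchShiftLog2fc scale of the cohort-wide additive log2-mean shift
#'   distinguishing cohorts.
#' @param lrtSampleSd standard deviation of the per-sample latent signaling
#'   factor shared by ligand, receptor and targets of a planted interaction.
#' @param libsizeSdlog sdlog of the log-normal per-cell library-size factor.
#' @param seed integer seed controlling the prior, truth and shared baselines.
#' @return A validated list of class \code{SimConfig}.
#' @examples
#' cfg <- simConfig(nGenes = 300, nTfs = 10, nPlantedTfs = 2)
#' @export
simConfig <- function(nGenes = 1200L,
                      nSamplesCase = 8L,
                      nSamplesControl = 8L,
                      cellTypes = c(astrocytes = "sender", microglia = "sender",
                                    oligodendrocytes = "sender", OPC = "sender",
                                    excitatory = "receiver", inhibitory = "receiver"),
                      cellsPerSamplePerType = c(20L, 40L),
                      nbDispersion = 2,
                      baselineLogMeanRange = c(-2, 3),
                      nPlantedLR = 10L,
                      lrEffectLog2fc = 2,
                      nTargetsPerLigand = 5L,
                      nTfs = 50L,
                      nPlantedTfs = 10L,
                      targetsPerTf = 20L,
                      tfActivityShift = 1,
                      sexEffectLog2fc = 1,
                      sexGeneFraction = 0.05,
                      batchShiftLog2fc = 0.25,
                      lrtSampleSd = 0.3,
                      libsizeSdlog = 0.3,
                      seed = 1L) {
    cfg <- list(nGenes = .assertCount(nGenes, "nGenes"),
                nSamplesCase = .assertCount(nSamplesCase, "nSamplesCase"),
                nSamplesControl = .assertCount(nSamplesControl, "nSamplesControl"),
                cellTypes = cellTypes,
                cellsPerSamplePerType = as.integer(cellsPerSamplePerType),
                nbDispersion = .assertPositive(nbDispersion, "nbDispersion"),
                baselineLogMeanRange = as.numeric(baselineLogMeanRange),
                nPlantedLR = .assertCount(nPlantedLR, "nPlantedLR"),
                lrEffectLog2fc = lrEffectLog2fc,
                nTargetsPerLigand = .assertCount(nTargetsPerLigand, "nTargetsPerLigand"),
                nTfs = .assertCount(nTfs, "nTfs"),
                nPlantedTfs = .assertCount(nPlantedTfs, "nPlantedTfs", min = 0),
                targetsPerTf = .assertCount(targetsPerTf, "targetsPerTf"),
                tfActivityShift = tfActivityShift,
                sexEffectLog2fc = sexEffectLog2fc,
                sexGeneFraction = sexGeneFraction,
                batchShiftLog2fc = batchShiftLog2fc,
                lrtSampleSd = lrtSampleSd,
                libsizeSdlog = libsizeSdlog,
                seed = as.integer(seed))
    class(cfg) <- "SimConfig"
    validateSimConfig(cfg)
    cfg
}

#' Validate a simulation configuration
#'
#' @param config a \code{SimConfig}.
#' @return Invisibly \code{TRUE}; otherwise an error naming the offending field.
#' @export
validateSimConfig <- function(config) {
    roles <- config$cellTypes
    if (is.null(names(roles)) || !all(roles %in% c("sender", "receiver", "other")))
        stop("'cellTypes' must be a named vector of roles sender/receiver/other")
    if (!any(roles == "sender") || !any(roles == "receiver"))
        stop("'cellTypes' needs at least one sender and one receiver")
    r <- config$cellsPerSamplePerType
    if (length(r) != 2 || any(r < 1) || r[1] > r[2])
        stop("'cellsPerSamplePerType' must be an increasing positive range")
    b <- config$baselineLogMeanRange
    if (length(b) != 2 || b[1] > b[2])
        stop("'baselineLogMeanRange' must be an interval")
    if (config$sexGeneFraction < 0 || config$sexGeneFraction > 1)
        stop("'sexGeneFraction' must lie in [0, 1]")
    pools <- .genePools(config, check = TRUE)
    if (config$nPlantedLR > length(pools$ligands))
        stop("'nPlantedLR' exceeds the available ligand pool")
    if (config$nPlantedTfs > config$nTfs)
        stop("'nPlantedTfs' must not exceed 'nTfs'")
    invisible(TRUE)
}

# Partition the gene universe into functional pools. LRT targets, the
# regulatory-potential support and TF-regulon targets are mutually disjoint so
# planted communication and planted TF activity stay identifiable: the
# generator is a validation instrument and each planted signal class must be
# attributable to its own ground truth.
.genePools <- function(config, check = FALSE) {
    n <- config$nGenes
    nLig <- max(20L, 2L * config$nPlantedLR)
    nRec <- nLig
    nMed <- max(10L, 2L * config$nPlantedLR)
    nLrtTargets <- config$nPlantedLR * config$nTargetsPerLigand
    used <- nLig + nRec + config$nTfs + nMed + nLrtTargets
    rest <- n - used
    nPot <- max(50L, round(rest * 0.3))
    if (check && rest - nPot < max(config$targetsPerTf, 50L))
        stop(sprintf("'nGenes' too small: %d genes needed for roles plus free pools",
                     used + nPot + max(config$targetsPerTf, 50L)))
    genes <- sprintf("G%05d", seq_len(n))
    idx <- 0L
    take <- function(k) { on.exit(idx <<- idx + k); genes[idx + seq_len(k)] }
    list(genes = genes,
         ligands = take(nLig),
         receptors = take(nRec),
         tfs = take(config$nTfs),
         mediatorPool = take(nMed),
         lrtTargetPool = take(nLrtTargets),
         potentialPool = take(nPot),
         tfTargetPool = genes[(used + nPot + 1L):n])
}

#' Generate synthetic prior knowledge and matching ground truth
#'
#' Builds the five prior tables (ligand-receptor network, regulatory-potential
#' matrix, weighted signaling digraph, signed TF regulons, pathway weights)
#' together with the planted ground truth they encode: the planted
#' ligand-receptor pairs are in the network, their targets sit in the top
#' decile of the ligand's regulatory-potential row, every planted triple has a
#' receptor-to-target path through a planted mediator in the signaling graph,
#' and the planted TFs carry signed activity shifts. Deterministic given
#' \code{config$seed}.
#'
#' @param config a \code{SimConfig}.
#' @return \code{list(prior = PriorKnowledge, truth = GroundTruth)}.
#' @examples
#' pt <- generatePrior(simConfig(nGenes = 400, nTfs = 10, nPlantedTfs = 2))
#' pt$prior
#' @export
generatePrior <- function(config) {
    validateSimConfig(config)
    set.seed(config$seed)
    pools <- .genePools(config)
    senders <- names(config$cellTypes)[config$cellTypes == "sender"]
    receivers <- names(config$cellTypes)[config$cellTypes == "receiver"]

    nP <- config$nPlantedLR
    plantedLig <- pools$ligands[seq_len(nP)]
    plantedRec <- pools$receptors[seq_len(nP)]
    # cycle senders fast and receivers in blocks so senders reach several
    # receivers (keeps receiver-level similarity tables nondegenerate)
    plantedSender <- senders[(seq_len(nP) - 1L) %% length(senders) + 1L]
    plantedReceiver <- receivers[((seq_len(nP) - 1L) %/% length(senders)) %%
                                     length(receivers) + 1L]
    direction <- ifelse(seq_len(nP) %% 4L == 0L, "up_in_control", "up_in_case")

    # decoy LR pairs never reuse planted ligands/receptors, so planted pairs
    # stay uniquely attributable
    freeLig <- setdiff(pools$ligands, plantedLig)
    freeRec <- setdiff(pools$receptors, plantedRec)
    nDecoy <- min(60L, length(freeLig) * length(freeRec))
    decoy <- unique(data.frame(
        ligand = sample(freeLig, nDecoy, replace = TRUE),
        receptor = sample(freeRec, nDecoy, replace = TRUE)))
    lrNetwork <- rbind(data.frame(ligand = plantedLig, receptor = plantedRec), decoy)
    rownames(lrNetwork) <- NULL

    # planted downstream targets, disjoint across ligands
    targetList <- split(pools$lrtTargetPool,
                        rep(seq_len(nP), each = config$nTargetsPerLigand))

    # sparse regulatory potential: each ligand regulates a limited gene
    # program drawn from a dedicated pool, planted targets in the top decile
    allLig <- unique(lrNetwork$ligand)
    nSupport <- min(60L, length(pools$potentialPool))
    rp <- matrix(0, nrow = length(allLig), ncol = config$nGenes,
                 dimnames = list(allLig, pools$genes))
    for (lig in allLig)
        rp[lig, sample(pools$potentialPool, nSupport)] <-
            stats::runif(nSupport, 0.05, 0.8)
    for (i in seq_len(nP))  # planted targets drawn from the row's top decile
        rp[plantedLig[i], targetList[[i]]] <-
            stats::runif(config$nTargetsPerLigand, 0.9, 1)

    # signaling digraph: ligand -> receptor -> mediator -> targets, plus a
    # weaker direct receptor -> target edge and background noise edges
    mediators <- pools$mediatorPool[seq_len(nP)]
    nTfMed <- min(4L, config$nPlantedTfs, nP)
    if (nTfMed > 0)  # some relays are TFs so mediator-TF activity is exercised
        mediators[seq_len(nTfMed)] <- pools$tfs[seq_len(nTfMed)]
    edges <- list()
    for (i in seq_len(nP)) {
        tg <- targetList[[i]]
        edges[[i]] <- rbind(
            data.frame(source = plantedLig[i], dest = plantedRec[i],
                       weight = stats::runif(1, 0.85, 0.95)),
            data.frame(source = plantedRec[i], dest = mediators[i],
                       weight = stats::runif(1, 0.75, 0.95)),
            data.frame(source = mediators[i], dest = tg,
                       weight = stats::runif(length(tg), 0.75, 0.95)),
            data.frame(source = plantedRec[i], dest = tg[1],
                       weight = stats::runif(1, 0.2, 0.4)))
    }
    pool <- pools$tfTargetPool
    noise <- data.frame(source = sample(pool, 300L, replace = TRUE),
                        dest = sample(pool, 300L, replace = TRUE),
                        weight = stats::runif(300L, 0.05, 0.6))
    noise <- noise[noise$source != noise$dest, ]
    se <- do.call(rbind, c(edges, list(noise)))
    se <- se[!duplicated(se[, c("source", "dest")]), ]
    rownames(se) <- NULL

    # signed TF regulons over genes disjoint from planted LRT machinery
    tfPool <- pools$tfTargetPool
    regulons <- do.call(rbind, lapply(seq_len(config$nTfs), function(i) {
        data.frame(tf = pools$tfs[i],
                   target = sample(tfPool, config$targetsPerTf),
                   mode = sample(c(-1, 1), config$targetsPerTf, replace = TRUE))
    }))

    nPath <- 4L
    pathGenes <- lapply(seq_len(nPath), function(i)
        sample(pools$genes, min(120L, config$nGenes)))
    pathways <- do.call(rbind, lapply(seq_len(nPath), function(i) {
        g <- pathGenes[[i]]
        data.frame(pathway = sprintf("PW%02d", i), gene = g,
                   weight = stats::rnorm(length(g)),
                   p_rank = sample(seq_along(g)))
    }))

    prior <- PriorKnowledge(lrNetwork = lrNetwork, regulatoryPotential = rp,
                            signalingEdges = se, tfRegulons = regulons,
                            pathwayWeights = pathways)

    base <- stats::runif(config$nGenes, config$baselineLogMeanRange[1],
                         config$baselineLogMeanRange[2])
    names(base) <- pools$genes
    sexGenes <- if (config$sexGeneFraction > 0)
        sample(pools$genes, round(config$sexGeneFraction * config$nGenes))
    else character()

    plantedTriples <- do.call(rbind, lapply(seq_len(nP), function(i) {
        data.frame(sender = plantedSender[i], receiver = plantedReceiver[i],
                   ligand = plantedLig[i], receptor = plantedRec[i],
                   target = targetList[[i]], direction = direction[i])
    }))
    rownames(plantedTriples) <- NULL

    sgn <- ifelse(direction == "up_in_case", 1, -1) * config$lrEffectLog2fc
    plantedDe <- rbind(
        data.frame(cell_type = plantedSender, gene = plantedLig, log2fc = sgn),
        data.frame(cell_type = plantedReceiver, gene = plantedRec, log2fc = sgn),
        do.call(rbind, lapply(seq_len(nP), function(i)
            data.frame(cell_type = plantedReceiver[i], gene = targetList[[i]],
                       log2fc = sgn[i]))))
    rownames(plantedDe) <- NULL

    tfShifts <- numeric(0)
    if (config$nPlantedTfs > 0) {
        tfShifts <- rep_len(c(1, -1), config$nPlantedTfs) * config$tfActivityShift
        names(tfShifts) <- pools$tfs[seq_len(config$nPlantedTfs)]
    }

    truth <- new("GroundTruth", plantedLRT = plantedTriples,
                 plantedTfShifts = tfShifts, plantedDeGenes = plantedDe,
                 sexGenes = sexGenes, baseLogMean = base,
                 mediators = data.frame(ligand = plantedLig,
                                        receptor = plantedRec,
                                        mediator = mediators))
    list(prior = prior, truth = truth)
}

#' Generate one synthetic cohort of annotated counts
#'
#' Draws negative-binomial counts whose log2 means combine the shared per-gene
#' baselines with the planted effects recorded in \code{truth}: ligand shifts
#' in sender cells, receptor and target shifts in receiver cells (in the
#' direction's condition), mode-signed TF-regulon shifts in case receivers, a
#' sex effect on a designated gene subset, a per-sample latent signaling
#' factor shared within each planted interaction, a cohort-wide batch shift
#' drawn from \code{cohortSeed}, and log-normal per-cell library-size factors.
#'
#' @param config a \code{SimConfig}.
#' @param prior the matching \linkS4class{PriorKnowledge}.
#' @param truth the matching \linkS4class{GroundTruth}.
#' @param cohortSeed integer seed controlling cohort-level noise and batch.
#' @return A \linkS4class{CCCExperiment}.
#' @export
generateDataset <- function(config, prior, truth, cohortSeed = config$seed + 1L) {
    genes <- names(truth@baseLogMean)
    if (!length(genes)) stop("truth carries no gene universe")
    bad <- setdiff(unique(truth@plantedDeGenes$gene), genes)
    if (length(bad))
        stop(sprintf("truth gene absent from gene universe: %s", bad[1]))
    set.seed(as.integer(cohortSeed))

    nGenes <- length(genes)
    geneIdx <- stats::setNames(seq_len(nGenes), genes)
    cts <- names(config$cellTypes)
    samples <- data.frame(
        sample_id = sprintf("S%02d", seq_len(config$nSamplesCase + config$nSamplesControl)),
        condition = rep(c("case", "control"),
                        c(config$nSamplesCase, config$nSamplesControl)))
    # sex alternates within each condition: balanced by construction
    samples$sex <- unsplit(lapply(split(seq_len(nrow(samples)), samples$condition),
                                  function(i) rep_len(c("F", "M"), length(i))),
                           samples$condition)

    # condition-level log2 offsets per (cell type, condition)
    off <- lapply(cts, function(ct) list(case = numeric(nGenes),
                                         control = numeric(nGenes)))
    names(off) <- cts
    de <- truth@plantedDeGenes
    if (nrow(de)) {
        for (k in seq_len(nrow(de))) {
            ct <- de$cell_type[k]
            if (!ct %in% cts) next
            cond <- if (de$log2fc[k] >= 0) "case" else "control"
            off[[ct]][[cond]][geneIdx[de$gene[k]]] <-
                off[[ct]][[cond]][geneIdx[de$gene[k]]] + abs(de$log2fc[k])
        }
    }
    # TF-regulon shifts act on receiver cell types in case samples
    receivers <- names(config$cellTypes)[config$cellTypes == "receiver"]
    if (length(truth@plantedTfShifts)) {
        reg <- prior@tfRegulons
        for (tf in names(truth@plantedTfShifts)) {
            rows <- reg[reg$tf == tf, ]
            shift <- rows$mode * truth@plantedTfShifts[[tf]]
            for (ct in receivers)
                off[[ct]]$case[geneIdx[rows$target]] <-
                    off[[ct]]$case[geneIdx[rows$target]] + shift
        }
    }

    sexVec <- numeric(nGenes)
    if (length(truth@sexGenes))
        sexVec[geneIdx[truth@sexGenes]] <- config$sexEffectLog2fc
    batch <- stats::rnorm(1, 0, config$batchShiftLog2fc)

    # per-sample latent signaling factor per planted LR pair
    pl <- unique(truth@plantedLRT[, c("sender", "receiver", "ligand",
                                      "receptor", "direction")])
    nPairs <- nrow(pl)
    fac <- if (nPairs) matrix(stats::rnorm(nPairs * nrow(samples), 0,
                                           config$lrtSampleSd),
                              nPairs, nrow(samples)) else
        matrix(0, 0, nrow(samples))
    pairGenes <- lapply(seq_len(nPairs), function(i) {
        tr <- truth@plantedLRT
        sel <- tr$ligand == pl$ligand[i] & tr$receptor == pl$receptor[i]
        list(senderGenes = geneIdx[pl$ligand[i]],
             receiverGenes = geneIdx[c(pl$receptor[i], unique(tr$target[sel]))])
    })

    ncellRange <- config$cellsPerSamplePerType
    blocks <- vector("list", nrow(samples) * length(cts))
    metas <- vector("list", length(blocks))
    b <- 0L
    for (s in seq_len(nrow(samples))) {
        cond <- samples$condition[s]
        isM <- samples$sex[s] == "M"
        for (ct in cts) {
            nc <- if (ncellRange[1] == ncellRange[2]) ncellRange[1] else
                sample(ncellRange[1]:ncellRange[2], 1)
            lm2 <- truth@baseLogMean + off[[ct]][[cond]] + batch +
                if (isM) sexVec else 0
            role <- config$cellTypes[[ct]]
            for (i in seq_len(nPairs)) {
                pg <- pairGenes[[i]]
                if (ct == pl$sender[i])
                    lm2[pg$senderGenes] <- lm2[pg$senderGenes] + fac[i, s]
                if (ct == pl$receiver[i])
                    lm2[pg$receiverGenes] <- lm2[pg$receiverGenes] + fac[i, s]
            }
            lib <- stats::rlnorm(nc, 0, config$libsizeSdlog)
            mu <- outer(2^lm2, lib)
            cntv <- stats::rnbinom(length(mu), mu = as.vector(mu),
                                   size = config$nbDispersion)
            b <- b + 1L
            blocks[[b]] <- matrix(cntv, nrow = nGenes)
            metas[[b]] <- data.frame(sample_id = samples$sample_id[s],
                                     condition = cond, cell_type = ct,
                                     sex = samples$sex[s])[rep(1, nc), ]
        }
    }
    counts <- do.call(cbind, blocks)
    rownames(counts) <- genes
    meta <- do.call(rbind, metas)
    meta$barcode <- sprintf("C%06d_%s", seq_len(nrow(meta)), cohortSeed)
    rownames(meta) <- NULL
    CCCExperiment(methods::as(counts, "CsparseMatrix"), meta)
}

#' Generate a full two-cohort synthetic study
#'
#' One prior and one ground truth shared by two cohorts generated with
#' distinct cohort seeds (so the cohorts share planted biology but differ in
#' sampling noise and batch shift), mirroring an original-plus-replication
#' study design.
#'
#' @param config a \code{SimConfig}.
#' @return \code{list(prior, truth, cohortA, cohortB)}.
#' @examples
#' study <- generateStudy(simConfig(nGenes = 300, nTfs = 8, nPlantedTfs = 2,
#'                                  nSamplesCase = 2, nSamplesControl = 2,
#'                                  cellsPerSamplePerType = c(5, 8)))
#' @export
generateStudy <- function(config) {
    pt <- generatePrior(config)
    seeds <- (config$seed + c(7919L, 15838L)) %% .Machine$integer.max
    cohortA <- generateDataset(config, pt$prior, pt$truth, cohortSeed = seeds[1])
    cohortB <- generateDataset(config, pt$prior, pt$truth, cohortSeed = seeds[2])
    list(prior = pt$prior, truth = pt$truth, cohortA = cohortA, cohortB = cohortB)
}
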