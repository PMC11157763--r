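#' Pipeline configuration
#'
#' Collects every threshold the analysis uses, the sender/receiver roles, the
#' prioritization weights and the seed. Defaults follow the method's stated
#' operating point: 0.5 log2FC with unadjusted p 0.05 for differential
#' expression, top-250 regulatory-potential targets, dual correlation
#' threshold 0.33, minimum 5 cells per cell type per sample, minimum 5
#' targets per regulator, top 2 signaling regulators, top-500 responsive
#' pathway genes, equal prioritization weights.
#'
#' @param senders,receivers cell-type labels (must be disjoint).
#' @param logfcMin,pMax,topNTargets,rMin,minCells,minTargets,topKRegulators,
#'   pathwayTopN thresholds; see Details above.
#' @param weights eight non-negative prioritization weights (default equal).
#' @param useSexCovariate include sex in the DE model; default TRUE.
#' @param correlationSignal \code{"product"} or \code{"separate"}.
#' @param simulate run on a synthetic study generated from \code{sim}.
#' @param sim a \code{SimConfig} when \code{simulate}.
#' @param cohorts when not simulating: named list of
#'   \linkS4class{CCCExperiment}s (or lists with \code{mtx}, \code{genes},
#'   \code{cells} paths).
#' @param prior a \linkS4class{PriorKnowledge} or a directory for [readPrior()]
#'   (ignored when simulating).
#' @param seed integer seed.
#' @param outputDir optional directory; when set, [runPipeline()] writes CSV
#'   artifacts there.
#' @return A validated list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(senders = c("astrocytes", "microglia",
                                       "oligodendrocytes", "OPC"),
                           receivers = c("excitatory", "inhibitory"),
                           logfcMin = 0.5, pMax = 0.05, topNTargets = 250L,
                           rMin = 0.33, minCells = 5L, minTargets = 5L,
                           topKRegulators = 2L, pathwayTopN = 500L,
                           weights = NULL, useSexCovariate = TRUE,
                           correlationSignal = c("product", "separate"),
                           simulate = TRUE, sim = simConfig(),
                           cohorts = NULL, prior = NULL,
                           seed = 1L, outputDir = NULL) {
    if (length(intersect(senders, receivers)))
        stop("senders and receivers must be disjoint")
    if (!length(receivers)) stop("'receivers' must be nonempty")
    if (!length(senders)) stop("'senders' must be nonempty")
    for (v in c(logfcMin = logfcMin, pMax = pMax, topNTargets = topNTargets,
                rMin = rMin, minTargets = minTargets,
                topKRegulators = topKRegulators, pathwayTopN = pathwayTopN))
        if (v <= 0) stop("all thresholds must be positive")
    if (minCells < 0) stop("'minCells' must be non-negative")
    cfg <- list(senders = senders, receivers = receivers, logfcMin = logfcMin,
                pMax = pMax, topNTargets = as.integer(topNTargets),
                rMin = rMin, minCells = as.integer(minCells),
                minTargets = as.integer(minTargets),
                topKRegulators = as.integer(topKRegulators),
                pathwayTopN = as.integer(pathwayTopN), weights = weights,
                useSexCovariate = useSexCovariate,
                correlationSignal = match.arg(correlationSignal),
                simulate = simulate, sim = sim, cohorts = cohorts,
                prior = prior, seed = as.integer(seed), outputDir = outputDir)
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Single-cohort analysis: pseudobulk to filtered, prioritized interactions
#'
#' Runs pseudobulk aggregation, unit filtering, per-cell-type differential
#' expression, candidate ligand-receptor detection, target inference with
#' ligand-activity scoring, prioritization and the dual correlation filter
#' for one cohort.
#'
#' @param data a \linkS4class{CCCExperiment}.
#' @param prior a \linkS4class{PriorKnowledge}.
#' @param config a \code{PipelineConfig}.
#' @return list with \code{pb} (filtered pseudobulk), \code{de} (named list
#'   of DETables), \code{candidates}, \code{lrt} (filtered table),
#'   \code{funnel} (stage counts).
#' @export
analyzeCohort <- function(data, prior, config = pipelineConfig()) {
    pb <- filterUnits(pseudobulk(data), config$minCells)
    cd <- SummarizedExperiment::colData(pb)
    types <- intersect(c(config$senders, config$receivers),
                       unique(cd$cell_type))
    de <- lapply(stats::setNames(nm = types), function(ct)
        differentialExpression(pb, ct, config$useSexCovariate))
    cands <- candidateInteractions(de, prior,
                                   intersect(config$senders, types),
                                   intersect(config$receivers, types),
                                   config$logfcMin, config$pMax)
    lrt <- .assembleLRT(cands, de, prior, pb, config$topNTargets,
                        config$logfcMin, config$pMax)
    scored <- if (nrow(lrt)) prioritizeInteractions(lrt, config$weights) else lrt
    filtered <- correlationFilter(scored, pb, config$rMin,
                                  config$correlationSignal)
    list(pb = pb, de = de, candidates = cands, lrt = filtered,
         funnel = c(candidate_lr = nrow(cands), lrt_scored = nrow(scored),
                    lrt_filtered = nrow(filtered)))
}

#' Run the full two-cohort communication analysis
#'
#' Executes the end-to-end pipeline: per-cohort pseudobulk, differential
#' expression, ligand-receptor-target prioritization and correlation
#' filtering; per-cohort Jaccard similarity tables; cross-cohort intersection
#' into the high-confidence set; signaling-mediator identification for every
#' high-confidence interaction; combined Wald-statistic matrices and TF plus
#' pathway activity per receiver; and the mediator-TF activity subset.
#'
#' @param config a \code{PipelineConfig}.
#' @return A \code{ResultsBundle} list: \code{prior}, \code{truth} (when
#'   simulated), \code{cohorts} (per-cohort results), \code{similarity},
#'   \code{high_confidence}, \code{mediators}, \code{tf_activity},
#'   \code{pathway_activity}, \code{mediator_tf_activity},
#'   \code{provenance}.
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(sim = simConfig(nGenes = 400, nTfs = 10,
#'                                       nPlantedTfs = 2))
#' res <- runPipeline(cfg)
#' head(res$high_confidence$shared_lrt)
#' }
#' @export
runPipeline <- function(config = pipelineConfig()) {
    stopifnot(inherits(config, "PipelineConfig"))
    if (config$simulate) {
        study <- generateStudy(config$sim)
        prior <- study$prior
        truth <- study$truth
        cohortData <- list(cohortA = study$cohortA, cohortB = study$cohortB)
    } else {
        if (is.null(config$cohorts) || length(config$cohorts) < 1)
            stop("non-simulated runs need 'cohorts'")
        prior <- if (is.character(config$prior)) readPrior(config$prior)
                 else config$prior
        if (!methods::is(prior, "PriorKnowledge"))
            stop("'prior' must be a PriorKnowledge or a directory path")
        truth <- NULL
        cohortData <- lapply(config$cohorts, function(x) {
            if (methods::is(x, "CCCExperiment")) x
            else readCounts(x$mtx, x$genes, x$cells)
        })
    }
    cohorts <- lapply(cohortData, analyzeCohort, prior = prior, config = config)

    similarity <- lapply(cohorts, function(co) {
        lrt <- co$lrt
        if (!nrow(lrt)) return(list())
        sims <- list(receiver_receptor = receiverSimilarity(lrt, "receptor"),
                     receiver_target = receiverSimilarity(lrt, "target"))
        for (r in intersect(config$receivers, lrt$receiver))
            for (role in c("ligand", "receptor", "target"))
                sims[[paste("sender", role, r, sep = "_")]] <-
                    senderSimilarity(lrt, role, r)
        sims
    })

    hc <- if (length(cohorts) >= 2)
        do.call(highConfidenceSet, lapply(cohorts, `[[`, "lrt"))
    else list(shared_lr = NULL, shared_lrt = NULL)

    mediators <- if (!is.null(hc$shared_lrt) && nrow(hc$shared_lrt))
        mediatorsForLRTs(hc$shared_lrt, prior, config$topKRegulators)
    else list()

    tfAct <- pwAct <- medTfAct <- list()
    for (r in config$receivers) {
        tabs <- lapply(cohorts, function(co) co$de[[r]])
        tabs <- tabs[!vapply(tabs, is.null, logical(1))]
        if (!length(tabs)) next
        stats <- combineStats(tabs, r)
        regTf <- buildRegulonMatrix(prior, rownames(stats),
                                    config$minTargets, "tf")
        if (ncol(regTf))
            tfAct[[r]] <- mlmActivity(stats, regTf)
        regPw <- buildRegulonMatrix(prior, rownames(stats), config$minTargets,
                                    "pathway", config$pathwayTopN)
        if (ncol(regPw))
            pwAct[[r]] <- mlmActivity(stats, regPw)
        if (!is.null(tfAct[[r]]) && length(mediators)) {
            recMed <- mediators[hc$shared_lrt$receiver == r]
            if (length(recMed))
                medTfAct[[r]] <- mediatorTfActivity(tfAct[[r]], recMed)
        }
    }

    bundle <- list(prior = prior, truth = truth, cohorts = cohorts,
                   similarity = similarity, high_confidence = hc,
                   mediators = mediators, tf_activity = tfAct,
                   pathway_activity = pwAct,
                   mediator_tf_activity = medTfAct,
                   provenance = list(seed = config$seed,
                                     thresholds = config[c(
                                         "logfcMin", "pMax", "topNTargets",
                                         "rMin", "minCells", "minTargets",
                                         "topKRegulators", "pathwayTopN")],
                                     timestamp = format(Sys.time())))
    class(bundle) <- "ResultsBundle"
    if (!is.null(config$outputDir)) .writeBundle(bundle, config$outputDir)
    bundle
}

.writeBundle <- function(bundle, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(bundle$cohorts)) {
        co <- bundle$cohorts[[nm]]
        utils::write.csv(co$lrt, file.path(dir, sprintf("lrt_%s.csv", nm)),
                         row.names = FALSE)
        for (ct in names(co$de))
            utils::write.csv(co$de[[ct]],
                             file.path(dir, sprintf("de_%s_%s.csv", nm, ct)),
                             row.names = FALSE)
    }
    if (!is.null(bundle$high_confidence$shared_lr)) {
        utils::write.csv(bundle$high_confidence$shared_lr,
                         file.path(dir, "shared_lr.csv"), row.names = FALSE)
        utils::write.csv(bundle$high_confidence$shared_lrt,
                         file.path(dir, "shared_lrt.csv"), row.names = FALSE)
    }
    for (r in names(bundle$tf_activity))
        utils::write.csv(bundle$tf_activity[[r]],
                         file.path(dir, sprintf("tf_activity_%s.csv", r)),
                         row.names = FALSE)
    for (r in names(bundle$pathway_activity))
        utils::write.csv(bundle$pathway_activity[[r]],
                         file.path(dir, sprintf("pathway_activity_%s.csv", r)),
                         row.names = FALSE)
    jsonlite::write_json(bundle$provenance, file.path(dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}
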