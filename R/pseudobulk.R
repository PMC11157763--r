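#' Aggregate single-cell counts to sample-by-cell-type pseudobulk
#'
#' Sums counts over all cells of each observed (sample, cell type) unit,
#' enabling sample-level statistics. Unit metadata carries the sample's
#' condition and sex plus the number of contributing cells.
#'
#' @param data a \linkS4class{CCCExperiment}.
#' @return A \link[SummarizedExperiment]{SummarizedExperiment} with assay
#'   \code{counts} (genes x units) and colData columns \code{sample_id},
#'   \code{cell_type}, \code{condition}, \code{sex}, \code{n_cells}.
#' @examples
#' study <- generateStudy(simConfig(nGenes = 300, nTfs = 8, nPlantedTfs = 2,
#'                                  nSamplesCase = 2, nSamplesControl = 2,
#'                                  cellsPerSamplePerType = c(5, 8)))
#' pb <- pseudobulk(study$cohortA)
#' @export
pseudobulk <- function(data) {
    if (!methods::is(data, "CCCExperiment")) stop("'data' must be a CCCExperiment")
    if (ncol(data) == 0) stop("cannot pseudobulk an empty experiment")
    cd <- SummarizedExperiment::colData(data)
    unit <- paste(cd$sample_id, cd$cell_type, sep = "|")
    uu <- unique(unit)
    ind <- Matrix::sparseMatrix(i = seq_along(unit),
                                j = match(unit, uu), x = 1,
                                dims = c(length(unit), length(uu)))
    pbm <- as.matrix(SummarizedExperiment::assay(data, "counts") %*% ind)
    storage.mode(pbm) <- "integer"
    colnames(pbm) <- uu
    first <- match(uu, unit)
    meta <- S4Vectors::DataFrame(
        sample_id = cd$sample_id[first],
        cell_type = cd$cell_type[first],
        condition = cd$condition[first],
        sex = cd$sex[first],
        n_cells = as.integer(table(factor(unit, levels = uu))),
        row.names = uu)
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = pbm), colData = meta)
}

#' Drop pseudobulk units backed by too few cells
#'
#' Retains units with at least \code{minCells} contributing cells (inclusive
#' threshold) and messages the dropped units. Warns when a cell type loses
#' all of its units.
#'
#' @param pb a pseudobulk \code{SummarizedExperiment} from [pseudobulk()].
#' @param minCells minimum cells per cell type per sample; default 5.
#' @return The filtered pseudobulk object.
#' @export
filterUnits <- function(pb, minCells = 5L) {
    cd <- SummarizedExperiment::colData(pb)
    keep <- cd$n_cells >= minCells
    if (any(!keep))
        message(sprintf("filterUnits: dropping %d unit(s) with < %d cells: %s",
                        sum(!keep), minCells,
                        paste(rownames(cd)[!keep], collapse = ", ")))
    lost <- setdiff(unique(cd$cell_type), unique(cd$cell_type[keep]))
    if (length(lost))
        warning(sprintf("all units dropped for cell type(s): %s",
                        paste(lost, collapse = ", ")))
    pb[, keep]
}

#' Case-versus-control differential expression for one cell type
#'
#' Fits, per gene, an ordinary-least-squares model of log2(CPM + 1) on an
#' intercept plus a case indicator (plus a sex indicator when
#' \code{useSexCovariate}), over the pseudobulk units of the requested cell
#' type. The reported \code{log2fc} is the condition coefficient,
#' \code{wald_stat} its coefficient-to-standard-error ratio, and p-values are
#' two-sided from the t distribution on the residual degrees of freedom, with
#' Benjamini-Hochberg adjustment within the table. Genes with zero counts
#' across all units of the cell type are dropped.
#'
#' @param pb a pseudobulk \code{SummarizedExperiment}.
#' @param cellType cell-type label to test.
#' @param useSexCovariate include the sex indicator; default TRUE.
#' @return A \code{data.frame} (class \code{DETable}) with columns
#'   \code{gene}, \code{log2fc}, \code{wald_stat}, \code{p}, \code{p_adj} and
#'   attributes \code{cell_type}, \code{contrast}, \code{covariates}.
#' @export
differentialExpression <- function(pb, cellType, useSexCovariate = TRUE) {
    cd <- SummarizedExperiment::colData(pb)
    sel <- cd$cell_type == cellType
    if (!any(sel)) stop(sprintf("no pseudobulk units for cell type '%s'", cellType))
    cdx <- cd[sel, , drop = FALSE]
    nCase <- sum(cdx$condition == "case")
    nCtrl <- sum(cdx$condition == "control")
    if (nCase < 2 || nCtrl < 2)
        stop(sprintf("cell type '%s' needs >= 2 case and >= 2 control units (has %d + %d)",
                     cellType, nCase, nCtrl))
    m <- SummarizedExperiment::assay(pb, "counts")[, sel, drop = FALSE]
    keep <- rowSums(m) > 0
    m <- m[keep, , drop = FALSE]
    if (!nrow(m)) stop(sprintf("no expressed genes for cell type '%s'", cellType))
    y <- .logCPM(m)

    X <- cbind(intercept = 1, condition = as.numeric(cdx$condition == "case"))
    covariates <- character()
    if (useSexCovariate && length(unique(cdx$sex)) > 1) {
        X <- cbind(X, sex = as.numeric(cdx$sex == "M"))
        covariates <- "sex"
    }
    df <- nrow(X) - ncol(X)
    if (df <= 0)
        stop(sprintf("zero residual degrees of freedom for cell type '%s'", cellType))
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) stop("design matrix is rank deficient")
    B <- qr.coef(qrX, t(y))                       # p x genes
    resid <- t(y) - X %*% B
    s2 <- colSums(resid^2) / df
    unpiv <- order(qrX$pivot)
    XtXinv <- chol2inv(qr.R(qrX))[unpiv, unpiv, drop = FALSE]
    se <- sqrt(s2 * XtXinv[2, 2])
    coefs <- B["condition", ]
    stat <- ifelse(se > 0, coefs / se,
                   ifelse(abs(coefs) < 1e-12, 0, sign(coefs) * Inf))
    p <- ifelse(is.finite(stat), 2 * stats::pt(-abs(stat), df),
                ifelse(stat == 0, 1, 0))
    p[se == 0 & abs(coefs) < 1e-12] <- 1
    out <- data.frame(gene = rownames(y), log2fc = unname(coefs),
                      wald_stat = unname(stat), p = unname(p),
                      p_adj = stats::p.adjust(unname(p), method = "BH"))
    rownames(out) <- NULL
    attr(out, "cell_type") <- cellType
    attr(out, "contrast") <- c(case = "case", control = "control")
    attr(out, "covariates") <- covariates
    class(out) <- c("DETable", "data.frame")
    out
}
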