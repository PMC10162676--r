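#' Remove genes expressed in too few cells
#'
#' Retains exactly the genes with a nonzero count in at least `min_cells`
#' cells; the cell set is unchanged and the operation is idempotent. With
#' `min_cells = 0` this is the identity.
#'
#' @param x `SingleCellExperiment` or counts matrix.
#' @param min_cells minimum number of expressing cells (default 3, the
#'   published per-dataset pre-filter).
#' @return the filtered object, same class as the input.
#' @export
filterGenesMinCells <- function(x, min_cells = 3) {
    stopifnot(min_cells >= 0)
    counts <- .getCounts(x)
    prevalence <- Matrix::rowSums(counts > 0)
    keep <- prevalence >= min_cells
    if (!any(keep))
        warning("no gene is expressed in >= ", min_cells,
                " cells; returning an empty gene set")
    if (is(x, "SummarizedExperiment")) x[keep, ] else x[keep, , drop = FALSE]
}

#' Per-cell quality control on detected genes and mitochondrial fraction
#'
#' Removes cells with fewer than `min_genes` or more than `max_genes`
#' detected genes (count > 0), or with a mitochondrial count fraction above
#' `max_mito`. All inequalities are strict, as published: cells sitting
#' exactly on a boundary (2500 or 7500 detected genes, fraction exactly
#' 0.10) are kept. Mitochondrial genes are identified by a case-insensitive
#' prefix match (mouse `mt-` convention); if none is present the fraction
#' is defined as 0 with a warning.
#'
#' @param x `SingleCellExperiment` or counts matrix.
#' @param min_genes,max_genes detected-genes bounds (defaults 2500/7500).
#' @param max_mito mitochondrial fraction bound (default 0.10).
#' @param mito_prefix gene-symbol prefix (default `"mt-"`).
#' @return list with `sce` (or matrix), the surviving cells, and `report`,
#'   a [S4Vectors::DataFrame] over all input cells with columns
#'   `n_genes_detected`, `mito_fraction`, `pass`, `reasons` (comma-joined
#'   subset of `low_genes`, `high_genes`, `high_mito`; empty iff `pass`).
#' @export
qcFilterCells <- function(x, min_genes = 2500, max_genes = 7500,
                          max_mito = 0.10, mito_prefix = "mt-") {
    stopifnot(min_genes <= max_genes, max_mito >= 0, max_mito <= 1)
    counts <- .getCounts(x)
    detected <- Matrix::colSums(counts > 0)
    mito <- grepl(paste0("^", mito_prefix), rownames(counts),
                  ignore.case = TRUE)
    total <- Matrix::colSums(counts)
    if (!any(mito)) {
        warning("no '", mito_prefix,
                "'-prefixed genes present; mito_fraction set to 0")
        mito_fraction <- rep(0, ncol(counts))
    } else {
        mito_fraction <- as.numeric(
            Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(total, 1))
    }
    detected <- unname(detected)
    low <- detected < min_genes
    high <- detected > max_genes
    himito <- mito_fraction > max_mito
    reasons <- mapply(function(l, h, m)
        paste(c(if (l) "low_genes", if (h) "high_genes",
                if (m) "high_mito"), collapse = ","),
        low, high, himito)
    pass <- !(low | high | himito)
    report <- S4Vectors::DataFrame(
        barcode = colnames(counts),
        n_genes_detected = as.integer(detected),
        mito_fraction = mito_fraction,
        pass = pass, reasons = unname(reasons))
    rownames(report) <- colnames(counts)
    kept <- if (is(x, "SummarizedExperiment")) x[, pass]
            else x[, pass, drop = FALSE]
    list(sce = kept, report = report)
}

#' Library-size log-normalization
#'
#' Computes `log(1 + count * scale_factor / total)` per cell with natural
#' log (the referenced workflow's defaults), storing the result as a
#' `logcounts` assay. Zero counts map exactly to zero, and the per-cell
#' vector is invariant to rescaling that cell's counts.
#'
#' @param x `SingleCellExperiment` or counts matrix; every cell must have a
#'   positive total count (run QC first).
#' @param scale_factor target library size (default 10000, the scale on
#'   which all published thresholds live).
#' @return the input with a `logcounts` assay (or the normalized matrix when
#'   a matrix was given). `metadata(x)$normalization` records the scale
#'   factor and log base.
#' @export
normalizeLog <- function(x, scale_factor = 1e4) {
    counts <- .getCounts(x)
    total <- Matrix::colSums(counts)
    if (any(total <= 0))
        stop("cell(s) with zero total count: ",
             paste(head(colnames(counts)[total <= 0], 5), collapse = ", "),
             "; apply qcFilterCells() first")
    if (is(counts, "sparseMatrix")) {
        norm <- counts %*% Matrix::Diagonal(x = scale_factor / total)
        norm@x <- log1p(norm@x)
        dimnames(norm) <- dimnames(counts)
    } else {
        norm <- log1p(sweep(counts, 2L, scale_factor / total, "*"))
    }
    if (is(x, "SummarizedExperiment")) {
        SummarizedExperiment::assay(x, "logcounts") <- norm
        S4Vectors::metadata(x)$normalization <-
            list(scale_factor = scale_factor, log_base = exp(1))
        x
    } else norm
}
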