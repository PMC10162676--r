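# Internal helpers shared across modules.

# Evaluate `code` under a local RNG seed, restoring the caller's stream.
.withSeed <- function(seed, code) {
    if (is.null(seed)) return(force(code))
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
    force(code)
}

# Extract a counts matrix from a SingleCellExperiment/SummarizedExperiment
# or pass a plain matrix through. Always returns a matrix-like with
# dimnames.
.getCounts <- function(x) {
    if (is(x, "SummarizedExperiment")) {
        if (!"counts" %in% SummarizedExperiment::assayNames(x))
            stop("no 'counts' assay found")
        m <- SummarizedExperiment::assay(x, "counts")
    } else m <- x
    if (is.null(rownames(m)) || is.null(colnames(m)))
        stop("count matrix must carry gene symbols and barcodes as dimnames")
    m
}

# Extract normalized log-expression ("logcounts") or pass a matrix through.
.getNorm <- function(x) {
    if (is(x, "SummarizedExperiment")) {
        if (!"logcounts" %in% SummarizedExperiment::assayNames(x))
            stop("no 'logcounts' assay found; run normalizeLog() first")
        m <- SummarizedExperiment::assay(x, "logcounts")
    } else m <- x
    if (is.null(rownames(m)) || is.null(colnames(m)))
        stop("expression matrix must carry gene symbols and barcodes as dimnames")
    m
}

# Fail with the list of rule genes absent from the matrix (never treat a
# missing rule gene as zero).
.checkGenesPresent <- function(genes, universe, what = "rule") {
    missing <- setdiff(genes, universe)
    if (length(missing))
        stop(sprintf("%s gene(s) absent from matrix: %s", what,
                     paste(missing, collapse = ", ")), call. = FALSE)
    invisible(TRUE)
}

# Resolve a group specification (barcodes or indices) to column indices.
.resolveCells <- function(group, barcodes) {
    if (is.character(group)) {
        idx <- match(group, barcodes)
        if (anyNA(idx))
            stop("unknown barcode(s): ",
                 paste(head(group[is.na(idx)], 5), collapse = ", "))
        idx
    } else if (is.logical(group)) {
        which(group)
    } else as.integer(group)
}

# Two-sided Wilcoxon rank-sum p-value following the package's exactness
# policy: exact enumeration (via the null distribution) when the pooled
# sample is small and tie-free, normal approximation with tie correction
# otherwise.
.rankSumP <- function(x, y, exact_max = 12L) {
    n1 <- length(x); n2 <- length(y)
    use_exact <- (n1 + n2) <= exact_max && !anyDuplicated(c(x, y))
    suppressWarnings(
        stats::wilcox.test(x, y, alternative = "two.sided",
                           exact = use_exact, correct = TRUE)$p.value)
}
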