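#' Read a 10x-style MTX triplet directory
#'
#' Reads `matrix.mtx`, `features.tsv` (or `genes.tsv`) and `barcodes.tsv`,
#' each optionally gzipped, into a [SingleCellExperiment][SingleCellExperiment::SingleCellExperiment]
#' with a `counts` assay oriented genes x cells. Gene symbols are taken from
#' the second column of the features file when present, else the first;
#' duplicate symbols are disambiguated by suffixing `.1`, `.2`, ... so that
#' rownames stay unique (all downstream thresholds are keyed by symbol).
#'
#' @param directory path containing the triplet.
#' @return a `SingleCellExperiment`; `rowData` keeps the original feature id
#'   and symbol columns.
#' @examples
#' sce <- makeFixture("two_groups_de")
#' d <- tempfile(); writeMTXTriplet(sce, d)
#' sce2 <- readMTXTriplet(d)
#' identical(as.matrix(counts(sce2)), as.matrix(counts(sce)))
#' @export
readMTXTriplet <- function(directory) {
    mtx <- .findFile(directory, "matrix.mtx")
    feat <- .findFile(directory, c("features.tsv", "genes.tsv"))
    bc <- .findFile(directory, "barcodes.tsv")

    m <- Matrix::readMM(mtx)
    features <- utils::read.delim(feat, header = FALSE,
                                  colClasses = "character")
    barcodes <- utils::read.delim(bc, header = FALSE,
                                  colClasses = "character")[[1L]]

    if (nrow(features) != nrow(m) || length(barcodes) != ncol(m))
        stop(sprintf(
            "dimension mismatch: matrix is %d x %d but features/barcodes have %d/%d entries",
            nrow(m), ncol(m), nrow(features), length(barcodes)))
    x <- m@x
    if (length(x) && (any(x < 0) || any(x != round(x))))
        stop("matrix entries must be non-negative integers (UMI counts)")
    if (anyDuplicated(barcodes))
        stop("barcodes must be unique")

    symbols <- if (ncol(features) >= 2L) features[[2L]] else features[[1L]]
    symbols <- make.unique(symbols, sep = ".")

    counts <- methods::as(m, "CsparseMatrix")
    dimnames(counts) <- list(symbols, barcodes)
    rd <- S4Vectors::DataFrame(feature_id = features[[1L]], symbol = symbols)
    rownames(rd) <- symbols
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts), rowData = rd)
}

.findFile <- function(directory, basenames) {
    for (b in basenames) for (f in c(b, paste0(b, ".gz"))) {
        p <- file.path(directory, f)
        if (file.exists(p)) return(p)
    }
    stop(sprintf("no %s(.gz) found in %s", paste(basenames, collapse = "/"),
                 directory))
}

#' Write a count matrix as an MTX triplet
#'
#' Writes `matrix.mtx`, `features.tsv` and `barcodes.tsv` (Matrix Market
#' coordinate format, 1-based indices) such that [readMTXTriplet()]
#' reproduces the matrix exactly, including gene and barcode order.
#'
#' @param x a `SingleCellExperiment` (its `counts` assay is written) or a
#'   genes x cells matrix with dimnames.
#' @param directory output directory, created if needed.
#' @param gzip compress the three files.
#' @return the directory, invisibly.
#' @export
writeMTXTriplet <- function(x, directory, gzip = FALSE) {
    counts <- .getCounts(x)
    if (!dir.exists(directory) &&
        !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create directory ", directory)
    sm <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix")
    ext <- if (gzip) ".gz" else ""
    mtx_path <- file.path(directory, "matrix.mtx")
    Matrix::writeMM(sm, mtx_path)
    if (gzip) {
        .gzipFile(mtx_path)
        mtx_path <- paste0(mtx_path, ".gz")
    }
    feature_id <- if (is(x, "SummarizedExperiment") &&
                      "feature_id" %in%
                          colnames(SummarizedExperiment::rowData(x)))
        SummarizedExperiment::rowData(x)$feature_id else rownames(counts)
    .writeTsv(data.frame(feature_id, rownames(counts), "Gene Expression"),
              file.path(directory, "features.tsv"), gzip)
    .writeTsv(data.frame(colnames(counts)),
              file.path(directory, "barcodes.tsv"), gzip)
    invisible(directory)
}

.writeTsv <- function(df, path, gzip) {
    con <- if (gzip) gzfile(paste0(path, ".gz"), "wb") else file(path, "wb")
    on.exit(close(con))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
}

.gzipFile <- function(path) {
    raw <- readBin(path, "raw", file.size(path))
    con <- gzfile(paste0(path, ".gz"), "wb")
    writeBin(raw, con)
    close(con)
    unlink(path)
}

#' Read gene sets from a GMT file
#'
#' Standard tab-delimited GMT: set name, description, then member genes.
#' Duplicate genes within a line are dropped keeping the first occurrence.
#'
#' @param path GMT file.
#' @return named list of character vectors; per-set descriptions are kept in
#'   the `"description"` attribute.
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("astro\tdoi\tFam107a\tCbs\tMlc1", f)
#' readGeneSets(f)
#' @export
readGeneSets <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    sets <- list(); descr <- character(0)
    for (i in seq_along(lines)) {
        fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
        if (length(fields) < 3L)
            stop(sprintf("GMT format error at line %d: expected >= 3 tab-delimited fields, found %d",
                         i, length(fields)))
        name <- fields[[1L]]
        if (name %in% names(sets))
            stop(sprintf("GMT format error at line %d: duplicate set name '%s'",
                         i, name))
        genes <- unique(fields[-(1:2)])
        genes <- genes[nzchar(genes)]
        if (!length(genes))
            stop(sprintf("GMT format error at line %d: set '%s' is empty",
                         i, name))
        sets[[name]] <- genes
        descr[[name]] <- fields[[2L]]
    }
    attr(sets, "description") <- descr
    sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description per-set description column (recycled).
#' @return `path`, invisibly.
#' @export
writeGeneSets <- function(sets, path, description = "na") {
    description <- rep_len(description, length(sets))
    lines <- vapply(seq_along(sets), function(i)
        paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
        character(1))
    writeLines(lines, path)
    invisible(path)
}

# Stable column order of the annotation CSV.
.annCols <- c("barcode", "cell_type", "type_ambiguous", "lineage",
              "hopx_stratum", "cycle_phase", "s_score", "g2m_score",
              "qc_pass", "qc_reasons")

#' Write a per-cell annotation table as CSV
#'
#' Writes one row per barcode with the stable column order `barcode,
#' cell_type, type_ambiguous, lineage, hopx_stratum, cycle_phase, s_score,
#' g2m_score, qc_pass, qc_reasons`, followed by one `auc_<set>` column per
#' scored signature (omitted when no signatures were scored). Columns absent
#' from the input are skipped.
#'
#' @param x an annotated `SingleCellExperiment` (its `colData` is written),
#'   a `DataFrame`, or a data.frame with a `barcode` column.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeAnnotations <- function(x, path) {
    df <- if (is(x, "SummarizedExperiment")) {
        d <- as.data.frame(SummarizedExperiment::colData(x))
        if (!"barcode" %in% names(d)) d$barcode <- colnames(x)
        d
    } else as.data.frame(x)
    if (!"barcode" %in% names(df))
        stop("annotation table must contain a 'barcode' column")
    if (anyDuplicated(df$barcode))
        stop("every barcode must appear exactly once")
    keep <- c(intersect(.annCols, names(df)),
              sort(grep("^auc_", names(df), value = TRUE)))
    out <- df[, keep, drop = FALSE]
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    invisible(path)
}

#' Read an annotation CSV written by [writeAnnotations()]
#'
#' Categorical columns are restored as factors over their canonical
#' domains.
#'
#' @param path CSV path.
#' @return a data.frame, one row per barcode.
#' @export
readAnnotations <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(barcode = "character"))
    domains <- list(
        cell_type = c("qNSC", "aNSC", "TAP", "NB", "OL", "Astro", "EC",
                      "unassigned"),
        lineage = c("pallial", "subpallial", "dual", "not_applicable"),
        hopx_stratum = c("high", "low", "intermediate"),
        cycle_phase = c("S", "G2M", "G1_G0"))
    for (nm in intersect(names(domains), names(df)))
        df[[nm]] <- factor(df[[nm]], levels = domains[[nm]])
    df
}

#' Build a SimConfig from a YAML file
#'
#' Reads a flat YAML mapping whose keys are [simConfig()] arguments.
#'
#' @param path YAML file.
#' @return a [SimConfig-class].
#' @export
simConfigFromYAML <- function(path) {
    cfg <- yaml::read_yaml(path)
    if (!is.null(cfg$type_proportions))
        cfg$type_proportions <- unlist(cfg$type_proportions)
    do.call(simConfig, cfg)
}
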