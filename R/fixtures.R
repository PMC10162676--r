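#' Small deterministic fixtures with hand-specified counts
#'
#' Constructed matrices for exact tests, reproducible without any RNG:
#' \describe{
#'   \item{`tiny_qc`}{10 cells x 7600 genes (sparse; the gene count must
#'     exceed 7500 so the published detected-genes boundaries are
#'     realizable). Exactly 3 cells violate the default QC rules, one per
#'     reason, and three more sit exactly on the 2500-gene, 7500-gene and
#'     0.10-mito boundaries (all kept, strict inequalities).}
#'   \item{`two_groups_de`}{6 + 6 cells x 50 genes; gene `DEgene01` is
#'     completely separated between the groups (tie-free), all other genes
#'     are identical across cells.}
#'   \item{`ranked_auc`}{1 cell x 20 genes with strictly decreasing
#'     counts, so the expression ranking equals the gene order.}
#'   \item{`cycle_demo`}{100 cells x 200 genes; 30 cells express the S
#'     program, 30 the G2/M program, 40 express no cycle gene at all.}
#' }
#'
#' @param name one of `"tiny_qc"`, `"two_groups_de"`, `"ranked_auc"`,
#'   `"cycle_demo"`.
#' @return a `SingleCellExperiment` with a `counts` assay and the planted
#'   truth in `colData` (where applicable).
#' @examples
#' makeFixture("ranked_auc")
#' @export
makeFixture <- function(name = c("tiny_qc", "two_groups_de", "ranked_auc",
                                 "cycle_demo")) {
    name <- match.arg(name)
    switch(name,
           tiny_qc = .fixtureTinyQC(),
           two_groups_de = .fixtureTwoGroupsDE(),
           ranked_auc = .fixtureRankedAUC(),
           cycle_demo = .fixtureCycleDemo())
}

.fixtureTinyQC <- function() {
    n_plain <- 7598L
    genes <- c(sprintf("Gene%05d", seq_len(n_plain)), "mt-Nd1", "mt-Co1")
    mt1 <- n_plain + 1L
    mt2 <- n_plain + 2L
    # per cell: number of plain genes detected (count 1 each) and the
    # mt-Nd1 count; chosen so each violator fails for exactly one reason
    cells <- list(
        clean1        = list(plain = 3000L, mito = 150L, viol = "none"),
        boundary_low  = list(plain = 2499L, mito = 130L, viol = "none"),
        low_violator  = list(plain = 2498L, mito = 130L, viol = "low_genes"),
        boundary_high = list(plain = 7499L, mito = 300L, viol = "none"),
        high_violator = list(plain = 7500L, mito = 300L, viol = "high_genes"),
        boundary_mito = list(plain = 2700L, mito = 300L, viol = "none"),
        mito_violator = list(plain = 2700L, mito = 334L, viol = "high_mito"),
        clean2        = list(plain = 2600L, mito = 140L, viol = "none"),
        clean3        = list(plain = 2800L, mito = 150L, viol = "none"),
        clean4        = list(plain = 3100L, mito = 160L, viol = "none"))
    i <- integer(0); j <- integer(0); x <- integer(0)
    for (c_idx in seq_along(cells)) {
        s <- cells[[c_idx]]
        rows <- c(seq_len(s$plain), mt1, if (c_idx == 1L) mt2)
        vals <- c(rep(1L, s$plain), s$mito, if (c_idx == 1L) 10L)
        i <- c(i, rows); j <- c(j, rep(c_idx, length(rows)))
        x <- c(x, vals)
    }
    counts <- Matrix::sparseMatrix(i = i, j = j, x = x,
                                   dims = c(length(genes), length(cells)),
                                   dimnames = list(genes, names(cells)))
    truth <- S4Vectors::DataFrame(
        barcode = names(cells),
        qc_violation = factor(
            vapply(cells, `[[`, character(1), "viol"),
            levels = c("none", "low_genes", "high_genes", "high_mito")),
        row.names = names(cells))
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts), colData = truth)
}

.fixtureTwoGroupsDE <- function() {
    n_genes <- 50L
    genes <- c("DEgene01", sprintf("Gene%05d", seq_len(n_genes - 1L)))
    counts <- matrix(2L, n_genes, 12L)
    counts[1L, ] <- c(20:25, 1:6)   # tie-free complete separation
    barcodes <- sprintf("cell%02d", 1:12)
    dimnames(counts) <- list(genes, barcodes)
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(
            barcode = barcodes,
            group = factor(rep(c("g1", "g2"), each = 6L)),
            row.names = barcodes),
        rowData = S4Vectors::DataFrame(
            symbol = genes, is_separated = seq_len(n_genes) == 1L,
            row.names = genes))
}

.fixtureRankedAUC <- function() {
    genes <- sprintf("G%02d", 1:20)
    counts <- matrix(20:1, 20L, 1L, dimnames = list(genes, "cell1"))
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts))
}

.fixtureCycleDemo <- function() {
    cc <- cellCycleGenes()
    s_genes <- cc$s[1:15]
    g2m_genes <- cc$g2m[1:15]
    bg <- sprintf("Bg%03d", seq_len(170L))
    genes <- c(s_genes, g2m_genes, bg)
    n <- 100L
    counts <- matrix(0L, length(genes), n)
    phase <- rep(c("S", "G2M", "G1_G0"), c(30L, 30L, 40L))
    counts[seq_along(s_genes), phase == "S"] <- 5L
    counts[length(s_genes) + seq_along(g2m_genes), phase == "G2M"] <- 5L
    for (g in seq_along(bg)) {
        row <- 30L + g
        counts[row, ] <- (g %% 3L) + ((g + seq_len(n)) %% 2L)
    }
    barcodes <- sprintf("cell%03d", seq_len(n))
    dimnames(counts) <- list(genes, barcodes)
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(
            barcode = barcodes,
            true_phase = factor(phase, levels = c("S", "G2M", "G1_G0")),
            row.names = barcodes))
}
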