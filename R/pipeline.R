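#' Run the full annotation pipeline
#'
#' Fixed stage order: gene prevalence filter, cell QC, log-normalization,
#' threshold-rule cell typing, lineage assignment, Hopx stratification,
#' cell-cycle scoring, signature AUC scoring. Each stage is idempotent on
#' its own output and the whole run is reproducible from `seed` (which
#' drives cell-cycle control sampling and, offset by one, the AUC
#' tie-break permutation).
#'
#' @param x `SingleCellExperiment` with a `counts` assay (e.g. from
#'   [readMTXTriplet()] or [simulateCounts()]).
#' @param rules,lineage_rule,strata,signatures,cycle_genes annotation
#'   structure; defaults are the published rules and signatures.
#' @param min_cells gene prevalence filter (default 3).
#' @param min_genes,max_genes,max_mito QC thresholds (defaults
#'   2500/7500/0.10).
#' @param scale_factor normalization scale factor (default 10000).
#' @param top_fraction AUC ranking fraction (default 0.05).
#' @param seed integer seed.
#' @return annotated `SingleCellExperiment` restricted to QC-passing cells,
#'   with `logcounts`, annotation columns in `colData` (`cell_type`,
#'   `type_ambiguous`, `lineage`, `hopx_stratum`, `cycle_phase`,
#'   `s_score`, `g2m_score`, `qc_pass`, `qc_reasons`, `auc_<signature>`),
#'   and the full QC report over all input cells in
#'   `metadata(x)$qc_report`.
#' @examples
#' \donttest{
#' sim <- simulateCounts(simConfig(n_cells = 300, n_genes = 3000, seed = 7))
#' ann <- runAnnotationPipeline(sim, seed = 7)
#' table(ann$cell_type)
#' }
#' @export
runAnnotationPipeline <- function(x,
                                  rules = defaultRuleSet(),
                                  lineage_rule = defaultLineageRule(),
                                  strata = hopxStrata(),
                                  signatures = signatureLibrary(),
                                  cycle_genes = cellCycleGenes(),
                                  min_cells = 3, min_genes = 2500,
                                  max_genes = 7500, max_mito = 0.10,
                                  scale_factor = 1e4,
                                  top_fraction = 0.05, seed = 1) {
    x <- filterGenesMinCells(x, min_cells)
    qc <- qcFilterCells(x, min_genes, max_genes, max_mito)
    x <- normalizeLog(qc$sce, scale_factor)

    typing <- classifyCellTypes(x, rules)
    lineage <- assignLineage(x, lineage_rule)
    hopx <- stratifyHopx(x, strata)
    cycle <- scoreCellCycle(x, cycle_genes$s, cycle_genes$g2m, seed = seed)
    aucs <- scoreSignatures(x, signatures, top_fraction, seed = seed + 1)

    cd <- SummarizedExperiment::colData(x)
    cd$barcode <- colnames(x)
    cd$cell_type <- typing$cell_type
    cd$type_ambiguous <- typing$type_ambiguous
    cd$lineage <- lineage
    cd$hopx_stratum <- hopx$stratum
    cd$cycle_phase <- cycle$phase
    cd$s_score <- cycle$s_score
    cd$g2m_score <- cycle$g2m_score
    kept <- qc$report[qc$report$pass, ]
    cd$qc_pass <- TRUE
    cd$qc_reasons <- kept$reasons
    if (ncol(aucs))
        for (nm in colnames(aucs)) cd[[paste0("auc_", nm)]] <- aucs[, nm]
    SummarizedExperiment::colData(x) <- cd
    S4Vectors::metadata(x)$qc_report <- qc$report
    x
}

#' Extract the per-cell annotation table
#'
#' @param x annotated `SingleCellExperiment` from [runAnnotationPipeline()].
#' @return its `colData` as a data.frame, one row per barcode.
#' @export
annotationTable <- function(x) {
    as.data.frame(SummarizedExperiment::colData(x))
}
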