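#' Score cell-cycle phase from S and G2/M marker expression
#'
#' For each marker set the score is the mean normalized expression of the
#' set genes minus the mean of control genes drawn from expression-matched
#' bins: all genes are ranked by dataset-mean expression and cut into
#' `n_bins` equal-frequency bins, and for every set gene up to `n_ctrl`
#' controls are sampled (seeded, without replacement, set genes excluded)
#' from its bin; the union of controls forms the reference. A cell is
#' called `S` when the S score is the strict maximum and positive, `G2M`
#' when the G2/M score is maximal and positive (ties between two positive
#' scores resolve to G2M), and `G1_G0` otherwise -- cells expressing
#' neither marker program are likely not cycling.
#'
#' @param x `SingleCellExperiment` with `logcounts`, or a normalized matrix.
#' @param s_genes,g2m_genes marker sets; defaults from [cellCycleGenes()].
#'   Genes absent from the matrix are dropped (an error if a whole set is
#'   absent).
#' @param n_bins number of expression bins (default 25).
#' @param n_ctrl controls per set gene (default 100, capped at bin size).
#' @param seed seed for control sampling.
#' @return [S4Vectors::DataFrame] with `s_score`, `g2m_score` and `phase`
#'   (factor S/G2M/G1_G0), one row per cell.
#' @export
scoreCellCycle <- function(x, s_genes = cellCycleGenes()$s,
                           g2m_genes = cellCycleGenes()$g2m,
                           n_bins = 25, n_ctrl = 100, seed = NULL) {
    norm <- .getNorm(x)
    universe <- rownames(norm)
    sets <- list(s = intersect(s_genes, universe),
                 g2m = intersect(g2m_genes, universe))
    for (nm in names(sets)) {
        dropped <- length(get(paste0(nm, "_genes"), inherits = TRUE)) -
            length(sets[[nm]])
        if (!length(sets[[nm]]))
            stop("no ", toupper(nm), " marker present in the matrix")
        if (dropped > 0)
            message(dropped, " ", toupper(nm),
                    " marker(s) absent from the matrix; dropped")
    }
    avg <- as.numeric(Matrix::rowMeans(norm))
    n <- length(avg)
    bin <- ceiling(rank(avg, ties.method = "first") * n_bins / n)
    set_genes <- unique(c(sets$s, sets$g2m))
    scores <- .withSeed(seed, {
        lapply(sets, function(gs) {
            ctrl <- unique(unlist(lapply(gs, function(g) {
                pool <- universe[bin == bin[match(g, universe)]]
                pool <- setdiff(pool, set_genes)
                if (!length(pool)) return(character(0))
                sample(pool, min(n_ctrl, length(pool)))
            })))
            set_mean <- Matrix::colMeans(norm[gs, , drop = FALSE])
            ctrl_mean <- if (length(ctrl))
                Matrix::colMeans(norm[ctrl, , drop = FALSE]) else 0
            as.numeric(set_mean - ctrl_mean)
        })
    })
    s_score <- scores$s
    g2m_score <- scores$g2m
    phase <- ifelse(s_score > g2m_score & s_score > 0, "S",
             ifelse(g2m_score >= s_score & g2m_score > 0, "G2M", "G1_G0"))
    out <- S4Vectors::DataFrame(
        s_score = s_score, g2m_score = g2m_score,
        phase = factor(phase, levels = c("S", "G2M", "G1_G0")))
    rownames(out) <- colnames(norm)
    out
}
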