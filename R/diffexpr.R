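#' Parameters for Wilcoxon differential expression
#'
#' @param min_pct minimum detection fraction in either group for a gene to
#'   be tested (default 0.1).
#' @param logfc_threshold minimum absolute average log fold change for a
#'   gene to be tested (default 0.25, natural-log scale).
#' @param p_cutoff significance cutoff of the enrichment filter (default
#'   0.05).
#' @param pct_enriched minimum detection fraction in the cluster of
#'   interest for the enrichment filter (default 0.25).
#' @param pseudocount pseudocount of the fold-change formula (default 1).
#' @return a list of class `DEParams`.
#' @export
deParams <- function(min_pct = 0.1, logfc_threshold = 0.25, p_cutoff = 0.05,
                     pct_enriched = 0.25, pseudocount = 1) {
    stopifnot(min_pct >= 0, min_pct <= 1, pct_enriched >= 0,
              pct_enriched <= 1, logfc_threshold >= 0, p_cutoff >= 0,
              pseudocount >= 0)
    structure(list(min_pct = min_pct, logfc_threshold = logfc_threshold,
                   p_cutoff = p_cutoff, pct_enriched = pct_enriched,
                   pseudocount = pseudocount), class = "DEParams")
}

#' Wilcoxon rank-sum differential expression between two groups
#'
#' Re-implements the standard single-cell marker test: genes are
#' pre-filtered to those detected in at least `min_pct` of either group
#' and with `|avg_logFC| >= logfc_threshold`, where
#' `avg_logFC = log(mean(expm1(x1)) + pc) - log(mean(expm1(x2)) + pc)`
#' on normalized values (natural log, pseudocount `pc`). Surviving genes
#' get a two-sided rank-sum p-value (exact for tie-free pooled samples of
#' at most 12, normal approximation with tie correction otherwise) and a
#' Bonferroni-adjusted p over the total number of genes in the matrix --
#' the pre-filter universe, as published.
#'
#' @param x `SingleCellExperiment` with `logcounts`, or a normalized matrix.
#' @param group1,group2 disjoint cell groups (barcodes, indices or logical).
#' @param params a [deParams()] list.
#' @param enriched_on_adjusted use adjusted rather than raw p in the
#'   enrichment flag (default FALSE; the published filter reads as raw p).
#' @return data.frame (one row per tested gene, ordered by p) with columns
#'   `gene`, `p_val`, `p_adj`, `avg_logFC`, `pct.1`, `pct.2`, `enriched`.
#'   Swapping the groups negates `avg_logFC`, swaps the detection columns
#'   and leaves p-values unchanged.
#' @export
wilcoxonDE <- function(x, group1, group2, params = deParams(),
                       enriched_on_adjusted = FALSE) {
    norm <- as.matrix(.getNorm(x))
    i1 <- .resolveCells(group1, colnames(norm))
    i2 <- .resolveCells(group2, colnames(norm))
    if (length(intersect(i1, i2)))
        stop("groups must be disjoint")
    if (!length(i1) || !length(i2))
        stop("both groups must be non-empty")
    if (length(i1) == 1L || length(i2) == 1L)
        warning("a group has a single cell; p-values are computed but fragile")
    e1 <- norm[, i1, drop = FALSE]
    e2 <- norm[, i2, drop = FALSE]
    pct1 <- rowMeans(e1 > 0)
    pct2 <- rowMeans(e2 > 0)
    pc <- params$pseudocount
    logfc <- log(rowMeans(expm1(e1)) + pc) - log(rowMeans(expm1(e2)) + pc)
    keep <- (pmax(pct1, pct2) >= params$min_pct) &
            (abs(logfc) >= params$logfc_threshold)
    genes <- rownames(norm)[keep]
    p <- vapply(which(keep), function(g) .rankSumP(e1[g, ], e2[g, ]),
                numeric(1))
    res <- data.frame(
        gene = genes, p_val = p,
        p_adj = bonferroniAdjust(p, nrow(norm)),
        avg_logFC = logfc[keep], pct.1 = pct1[keep], pct.2 = pct2[keep],
        row.names = NULL)
    pcol <- if (enriched_on_adjusted) res$p_adj else res$p_val
    res$enriched <- pcol < params$p_cutoff &
        res$avg_logFC >= params$logfc_threshold &
        res$pct.1 >= params$pct_enriched
    attr(res, "m_tests") <- nrow(norm)
    res[order(res$p_val, res$gene), ]
}

#' Bonferroni adjustment over a fixed test universe
#'
#' `p_adj = min(1, p * m)`: order-preserving, monotone, and idempotent at
#' the cap.
#'
#' @param p_values raw p-values in `[0, 1]`.
#' @param m size of the test universe; must be at least `length(p_values)`
#'   (the published correction uses the total number of genes in the
#'   dataset).
#' @return adjusted p-values.
#' @export
bonferroniAdjust <- function(p_values, m) {
    if (length(p_values) && (any(p_values < 0) || any(p_values > 1)))
        stop("p-values must lie in [0, 1]")
    if (m < length(p_values))
        stop("m must be >= the number of p-values")
    pmin(1, p_values * m)
}

#' Apply the published enrichment filter to a DE result
#'
#' Enriched genes satisfy `p < p_cutoff`, `avg_logFC >= logfc_threshold`
#' and detection in the cluster of interest `pct.1 >= pct_enriched`
#' (defaults 0.05 / 0.25 / 0.25). The published filter reads as raw p;
#' set `use_adjusted = TRUE` for the Bonferroni-adjusted mode.
#'
#' @param result data.frame from [wilcoxonDE()].
#' @param params a [deParams()] list.
#' @param use_adjusted filter on `p_adj` instead of `p_val`.
#' @return character vector of enriched gene symbols.
#' @export
filterEnriched <- function(result, params = deParams(),
                           use_adjusted = FALSE) {
    p <- if (use_adjusted) result$p_adj else result$p_val
    result$gene[p < params$p_cutoff &
                result$avg_logFC >= params$logfc_threshold &
                result$pct.1 >= params$pct_enriched]
}

#' Flag transcription factors / transcriptional regulators
#'
#' Membership against packaged DNA-binding and transcription-regulator
#' lists (static GMT fixtures; no ontology query). A gene is flagged when
#' it belongs to the union of the supplied sets.
#'
#' @param genes gene symbols.
#' @param tf_sets named list of membership sets; defaults to the packaged
#'   synthetic GO subsets (`tf_go_subsets_synthetic.gmt` -- an illustrative
#'   curated subset, not the full ontology terms).
#' @return data.frame with `gene`, `is_tf_tr`, and one logical column per
#'   set.
#' @export
annotateTfTr <- function(genes, tf_sets = NULL) {
    if (is.null(tf_sets))
        tf_sets <- readGeneSets(system.file(
            "extdata", "tf_go_subsets_synthetic.gmt",
            package = "svztyper", mustWork = TRUE))
    if (!length(tf_sets))
        stop("tf_sets must supply at least one membership set")
    out <- data.frame(gene = genes,
                      is_tf_tr = genes %in% unique(unlist(tf_sets)))
    for (nm in names(tf_sets)) out[[nm]] <- genes %in% tf_sets[[nm]]
    out
}

#' Mean detected genes per group and percent difference
#'
#' Reports, per group, the mean over cells of the number of detected genes
#' (count > 0), and the percent difference
#' `(1 - mean[A] / mean[B]) * 100` of the first group relative to the
#' second, with the orientation stated in `comparison`.
#'
#' @param x `SingleCellExperiment` with `counts`, or a raw counts matrix.
#' @param groups named list of two or more cell groups (barcodes/indices).
#' @return list with `means` (named), `percent_difference` (first vs
#'   second group; NA when fewer than two groups) and `comparison`.
#' @export
detectedGenesSummary <- function(x, groups) {
    counts <- .getCounts(x)
    detected <- Matrix::colSums(counts > 0)
    if (is.null(names(groups)))
        names(groups) <- paste0("group", seq_along(groups))
    means <- vapply(groups, function(g)
        mean(detected[.resolveCells(g, colnames(counts))]), numeric(1))
    pd <- if (length(means) >= 2)
        (1 - means[[1]] / means[[2]]) * 100 else NA_real_
    list(means = means, percent_difference = pd,
         comparison = if (length(means) >= 2)
             sprintf("%s relative to %s", names(means)[1], names(means)[2])
         else NA_character_)
}
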