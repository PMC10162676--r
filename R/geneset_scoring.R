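#' Rank genes per cell by decreasing expression
#'
#' Rank 1 is the most highly expressed gene in that cell. Ties are broken
#' by one seeded random permutation of the gene universe, applied
#' consistently across all cells of the run, so the ranking depends only on
#' the ranks of the expression values (any monotone transform of a cell's
#' values leaves it unchanged).
#'
#' @param x `SingleCellExperiment` with `logcounts`, or a normalized matrix.
#' @param seed seed for the tie-break permutation.
#' @return integer matrix (genes x cells) of ranks, with the permutation in
#'   the `"tie_permutation"` attribute.
#' @export
rankGenesPerCell <- function(x, seed = NULL) {
    norm <- .getNorm(x)
    norm <- as.matrix(norm)
    n <- nrow(norm)
    perm <- .withSeed(seed, sample.int(n))
    ranks <- matrix(0L, n, ncol(norm), dimnames = dimnames(norm))
    for (j in seq_len(ncol(norm))) {
        ord <- order(-norm[, j], perm)
        ranks[ord, j] <- seq_len(n)
    }
    attr(ranks, "tie_permutation") <- perm
    ranks
}

#' Recovery-curve AUC of a gene set within a cell's top-ranked genes
#'
#' Walks the top `k = ceiling(top_fraction * n_genes)` positions of a
#' cell's expression ranking and integrates the step recovery curve of the
#' gene set: `AUC = sum_{i=1..k} hits(i) / max_area`, where `hits(i)` is
#' the cumulative number of set genes at ranks `<= i` and
#' `max_area = sum_{i=1..k} min(i, m)` with `m = min(|set ∩ genes|, k)`.
#' A set fully packed at the top of the ranking scores exactly 1; a set
#' entirely outside the top `k` scores 0. Set genes absent from the matrix
#' are dropped with a message; an empty intersection yields `NA` (flagged,
#' not 0).
#'
#' @param ranking rank matrix from [rankGenesPerCell()] (or a single named
#'   rank vector for one cell).
#' @param genes gene set (character).
#' @param top_fraction fraction of the ranking considered (default 0.05).
#' @return numeric vector of scores in `[0, 1]`, one per cell.
#' @export
aucScore <- function(ranking, genes, top_fraction = 0.05) {
    stopifnot(top_fraction > 0, top_fraction <= 1)
    if (is.null(dim(ranking)))
        ranking <- matrix(ranking, ncol = 1,
                          dimnames = list(names(ranking), "cell"))
    n <- nrow(ranking)
    k <- as.integer(ceiling(top_fraction * n - 1e-9))  # guard FP on exact multiples
    present <- intersect(genes, rownames(ranking))
    dropped <- length(setdiff(genes, rownames(ranking)))
    if (dropped > 0)
        message(dropped, " signature gene(s) absent from the matrix; dropped")
    if (!length(present)) {
        warning("gene set has empty intersection with the matrix; score undefined")
        return(setNames(rep(NA_real_, ncol(ranking)), colnames(ranking)))
    }
    m <- min(length(present), k)
    max_area <- sum(pmin(seq_len(k), m))
    r <- ranking[present, , drop = FALSE]
    contrib <- pmax(k - r + 1L, 0L)          # area added by a hit at rank r
    setNames(as.numeric(colSums(contrib)) / max_area, colnames(ranking))
}

#' Score a library of gene signatures per cell
#'
#' Computes the recovery-curve AUC ([aucScore()]) of each signature in
#' every cell, using one shared seeded ranking.
#'
#' @param x `SingleCellExperiment` with `logcounts`, or a normalized matrix.
#' @param library named list of gene sets; default [signatureLibrary()]
#'   (astrocytic and deep-quiescence signatures).
#' @param top_fraction fraction of the ranking considered (default 0.05).
#' @param seed seed for the tie-break permutation.
#' @return numeric matrix cells x signatures (zero columns for an empty
#'   library).
#' @export
scoreSignatures <- function(x, library = signatureLibrary(),
                            top_fraction = 0.05, seed = NULL) {
    norm <- .getNorm(x)
    if (!length(library))
        return(matrix(numeric(0), ncol(norm), 0,
                      dimnames = list(colnames(norm), NULL)))
    ranking <- rankGenesPerCell(norm, seed = seed)
    out <- vapply(library, function(gs)
        aucScore(ranking, gs, top_fraction), numeric(ncol(norm)))
    if (is.null(dim(out)))
        out <- matrix(out, 1, dimnames = list(colnames(norm), names(library)))
    out
}

#' Compare signature scores between two groups of cells
#'
#' Per signature, reports group medians, the direction of the difference
#' and a two-sided Wilcoxon rank-sum p-value (exact when both groups have
#' at most 50 tie-free observations, normal approximation with tie
#' correction otherwise).
#'
#' @param scores matrix cells x signatures from [scoreSignatures()], or a
#'   numeric vector for a single signature.
#' @param group1,group2 cell barcodes (or indices) of the two groups.
#' @return data.frame with one row per signature: `median_1`, `median_2`,
#'   `direction` (`"group1>group2"` etc.), `p_value`, and `valid` (FALSE
#'   with `p_value = NA` when either group has fewer than 2 cells).
#' @export
compareScores <- function(scores, group1, group2) {
    if (is.null(dim(scores)))
        scores <- matrix(scores, ncol = 1,
                         dimnames = list(names(scores), "score"))
    i1 <- .resolveCells(group1, rownames(scores))
    i2 <- .resolveCells(group2, rownames(scores))
    res <- lapply(colnames(scores), function(sig) {
        a <- scores[i1, sig]; b <- scores[i2, sig]
        valid <- length(a) >= 2 && length(b) >= 2
        m1 <- median(a); m2 <- median(b)
        p <- if (valid) {
            n_ok <- length(a) <= 50 && length(b) <= 50
            suppressWarnings(wilcox.test(
                a, b, alternative = "two.sided",
                exact = n_ok && !anyDuplicated(c(a, b)),
                correct = TRUE)$p.value)
        } else NA_real_
        data.frame(signature = sig, median_1 = m1, median_2 = m2,
                   direction = if (m1 > m2) "group1>group2"
                               else if (m1 < m2) "group1<group2" else "equal",
                   p_value = p, valid = valid)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}
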