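#' Classify cells by boolean marker-threshold rules
#'
#' A cell receives a rule's label iff every clause of that rule holds on the
#' normalized log-expression matrix (strict inequalities). Cells matching no
#' rule are `"unassigned"`; cells matching more than one rule are resolved
#' by the RuleSet's priority order and flagged in `type_ambiguous`. A rule
#' gene absent from the matrix is an error (never silently treated as
#' zero).
#'
#' @param x `SingleCellExperiment` with `logcounts`, or a normalized matrix.
#' @param rules a [RuleSet-class]; default [defaultRuleSet()].
#' @return [S4Vectors::DataFrame] with columns `cell_type` (factor over the
#'   rule labels plus `"unassigned"`), `type_ambiguous` (logical) and
#'   `n_rules_matched`.
#' @examples
#' m <- matrix(0, 4, 2, dimnames = list(
#'     c("Slc1a3", "Prom1", "Egfr", "Foxj1"), c("c1", "c2")))
#' m[, 1] <- c(2, 1, 0, 0)
#' rs <- ruleSet(list(markerRule("qNSC", rownames(m),
#'     c("gt", "gt", "lt", "lt"), c(1, 0.6, 0.1, 0.1))))
#' classifyCellTypes(m, rs)$cell_type
#' @export
classifyCellTypes <- function(x, rules = defaultRuleSet()) {
    norm <- .getNorm(x)
    .checkGenesPresent(ruleGenes(rules), rownames(norm), "rule")
    labs <- vapply(rules@rules, function(r) r@label, character(1))
    matches <- matrix(FALSE, length(labs), ncol(norm),
                      dimnames = list(labs, colnames(norm)))
    for (r in rules@rules) {
        ok <- rep(TRUE, ncol(norm))
        for (j in seq_along(r@genes)) {
            v <- norm[r@genes[j], ]
            ok <- ok & (if (r@directions[j] == "gt") v > r@thresholds[j]
                        else v < r@thresholds[j])
        }
        matches[r@label, ] <- as.logical(ok)
    }
    n_matched <- colSums(matches)
    prio <- rules@priority
    first <- apply(matches[prio, , drop = FALSE], 2L,
                   function(m) which(m)[1L])
    label <- ifelse(is.na(first), "unassigned", prio[first])
    out <- S4Vectors::DataFrame(
        cell_type = factor(label, levels = c(prio, "unassigned")),
        type_ambiguous = n_matched > 1L,
        n_rules_matched = as.integer(n_matched))
    rownames(out) <- colnames(norm)
    out
}

#' Assign pallial/subpallial/dual lineage per cell
#'
#' `pallial` iff any pallial gene exceeds the threshold and every subpallial
#' gene lies strictly below it; `subpallial` is the mirror condition; `dual`
#' iff at least one gene on each side exceeds the threshold;
#' `not_applicable` otherwise. A value exactly equal to the threshold
#' satisfies neither a `>` nor a `<` clause.
#'
#' @param x `SingleCellExperiment` with `logcounts`, or a normalized matrix.
#' @param rule a [LineageRule-class]; default [defaultLineageRule()].
#' @return factor over `pallial`, `subpallial`, `dual`, `not_applicable`,
#'   named by barcode.
#' @export
assignLineage <- function(x, rule = defaultLineageRule()) {
    norm <- .getNorm(x)
    .checkGenesPresent(c(rule@pallial, rule@subpallial), rownames(norm),
                       "lineage")
    thr <- rule@threshold
    pal <- norm[rule@pallial, , drop = FALSE]
    sub <- norm[rule@subpallial, , drop = FALSE]
    any_pal <- Matrix::colSums(pal > thr) > 0
    any_sub <- Matrix::colSums(sub > thr) > 0
    all_pal_low <- Matrix::colSums(!(pal < thr)) == 0
    all_sub_low <- Matrix::colSums(!(sub < thr)) == 0
    out <- rep("not_applicable", ncol(norm))
    out[any_pal & all_sub_low] <- "pallial"
    out[any_sub & all_pal_low] <- "subpallial"
    out[any_pal & any_sub] <- "dual"
    setNames(factor(out, levels = c("pallial", "subpallial", "dual",
                                    "not_applicable")), colnames(norm))
}

#' Stratify cells by Hopx expression
#'
#' `high` iff normalized Hopx exceeds the high threshold (default 2.5),
#' `low` iff below the low threshold (default 0.4), `intermediate`
#' otherwise; strict comparisons, so Hopx exactly 2.5 is intermediate.
#'
#' @param x `SingleCellExperiment` with `logcounts`, or a normalized matrix.
#' @param strata a [HopxStrata-class]; default [hopxStrata()].
#' @param cells optional subset (barcodes, indices or logical); default all.
#' @return list with `stratum` (factor named by barcode over the subset)
#'   and `counts` (named integer vector high/low/intermediate).
#' @export
stratifyHopx <- function(x, strata = hopxStrata(), cells = NULL) {
    norm <- .getNorm(x)
    .checkGenesPresent(strata@gene, rownames(norm), "stratification")
    idx <- if (is.null(cells)) seq_len(ncol(norm))
           else .resolveCells(cells, colnames(norm))
    if (!length(idx)) stop("cell subset is empty")
    v <- as.numeric(norm[strata@gene, idx])
    s <- ifelse(v > strata@high, "high",
                ifelse(v < strata@low, "low", "intermediate"))
    stratum <- setNames(
        factor(s, levels = c("high", "low", "intermediate")),
        colnames(norm)[idx])
    list(stratum = stratum, counts = table(stratum))
}

#' Compare total RNA content of dual-lineage and single-lineage cells
#'
#' Doublets formed from a pallial and a subpallial cell masquerade as dual
#' cells but carry roughly twice the RNA; genuine dual cells do not. This
#' reports the mean total UMI count of each group, their ratio, and a
#' two-sided Wilcoxon rank-sum p-value. Interpretation is left to the
#' caller.
#'
#' @param x `SingleCellExperiment` with `counts`, or a raw counts matrix.
#' @param lineage per-cell lineage factor as returned by [assignLineage()]
#'   (aligned with the columns of `x`).
#' @return list with `mean_dual`, `mean_single`, `ratio`, `p_value`,
#'   `n_dual`, `n_single`, and `valid` (FALSE with `p_value = NA` when a
#'   group has fewer than 2 cells).
#' @export
rnaContentCheck <- function(x, lineage) {
    counts <- .getCounts(x)
    lineage <- as.character(lineage)
    stopifnot(length(lineage) == ncol(counts))
    total <- Matrix::colSums(counts)
    dual <- total[lineage == "dual"]
    single <- total[lineage %in% c("pallial", "subpallial")]
    valid <- length(dual) >= 2 && length(single) >= 2
    p <- if (valid) .rankSumP(dual, single) else NA_real_
    list(mean_dual = mean(dual), mean_single = mean(single),
         ratio = mean(dual) / mean(single), p_value = p,
         n_dual = length(dual), n_single = length(single), valid = valid)
}

#' Cell-type composition by group
#'
#' Counts and within-group fractions of cell types, after removing
#' `exclude_types`. The default exclusion of neuroblasts and
#' oligodendroglia mirrors the published cross-timepoint quantification
#' rule (they can originate from tissue adjacent to the microdissection);
#' pass `exclude_types = character(0)` for full compositions.
#'
#' @param annotations annotated `SingleCellExperiment`, `DataFrame` or
#'   data.frame with a `cell_type` column and the grouping column.
#' @param group_by grouping column: `"lineage"`, `"cell_type"` or
#'   `"sample"` (any present column is accepted; unknown columns error).
#' @param exclude_types cell types dropped before computing fractions
#'   (default `c("NB", "OL")`).
#' @return data.frame with columns `group`, `cell_type`, `count`,
#'   `fraction`, ordered by group then type (alphabetical); the applied
#'   exclusions are kept in the `"exclusions"` attribute. Fractions sum to
#'   1 within each group.
#' @export
computeComposition <- function(annotations, group_by = "cell_type",
                               exclude_types = c("NB", "OL")) {
    df <- if (is(annotations, "SummarizedExperiment"))
        as.data.frame(SummarizedExperiment::colData(annotations))
    else as.data.frame(annotations)
    if (!"cell_type" %in% names(df))
        stop("annotations must contain a 'cell_type' column")
    if (!group_by %in% names(df))
        stop("unknown group_by field: ", group_by)
    df <- df[!(as.character(df$cell_type) %in% exclude_types), , drop = FALSE]
    tab <- table(group = as.character(df[[group_by]]),
                 cell_type = as.character(df$cell_type))
    out <- as.data.frame(tab, stringsAsFactors = FALSE,
                         responseName = "count")
    out <- out[out$count > 0 | TRUE, ]
    totals <- tapply(out$count, out$group, sum)
    out$fraction <- out$count / as.numeric(totals[out$group])
    out <- out[order(out$group, out$cell_type), ]
    rownames(out) <- NULL
    attr(out, "exclusions") <- exclude_types
    out
}
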