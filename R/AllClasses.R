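#' @import methods
#' @importFrom stats median quantile rbinom rlnorm rnbinom runif setNames wilcox.test qbinom
#' @importFrom utils read.csv write.csv head
NULL

#' Boolean marker-threshold rule for one cell type
#'
#' A `MarkerRule` is a conjunction of clauses of the form
#' `gene > threshold` or `gene < threshold`, evaluated on normalized
#' log-expression. A cell receives the rule's label iff every clause holds;
#' comparisons are strict, so equality never satisfies a clause.
#'
#' @slot label single cell-type label, e.g. `"qNSC"`.
#' @slot genes character vector of gene symbols (unique within the rule).
#' @slot directions `"gt"` or `"lt"` per clause.
#' @slot thresholds non-negative numeric per clause, on the normalized-log
#'   scale.
#' @export
setClass("MarkerRule",
    representation(label = "character", genes = "character",
                   directions = "character", thresholds = "numeric"))

setValidity("MarkerRule", function(object) {
    msg <- NULL
    if (length(object@label) != 1L || !nzchar(object@label))
        msg <- c(msg, "label must be a single non-empty string")
    n <- length(object@genes)
    if (length(object@directions) != n || length(object@thresholds) != n)
        msg <- c(msg, "genes, directions and thresholds must have equal length")
    if (anyDuplicated(object@genes))
        msg <- c(msg, "genes must be unique within a rule")
    if (!all(object@directions %in% c("gt", "lt")))
        msg <- c(msg, "directions must be 'gt' or 'lt'")
    if (any(!is.finite(object@thresholds)) || any(object@thresholds < 0))
        msg <- c(msg, "thresholds must be finite and >= 0")
    if (is.null(msg)) TRUE else msg
})

#' Construct a MarkerRule
#'
#' @param label cell-type label.
#' @param genes gene symbols.
#' @param directions `"gt"`/`"lt"` per gene.
#' @param thresholds normalized-log thresholds per gene.
#' @return a [MarkerRule-class] object.
#' @examples
#' markerRule("OL", c("Pdgfra", "Sox10"), c("gt", "gt"), c(0.5, 0.5))
#' @export
markerRule <- function(label, genes, directions, thresholds) {
    new("MarkerRule", label = label, genes = as.character(genes),
        directions = as.character(directions),
        thresholds = as.numeric(thresholds))
}

#' An ordered collection of MarkerRules
#'
#' Houses the classifier's rules together with the tie-break priority used
#' when a cell satisfies more than one rule (the most differentiated
#' compatible identity wins; see [classifyCellTypes()]).
#'
#' @slot rules list of [MarkerRule-class] objects with unique labels.
#' @slot priority character permutation of the rule labels; earlier wins.
#' @export
setClass("RuleSet", representation(rules = "list", priority = "character"))

setValidity("RuleSet", function(object) {
    msg <- NULL
    if (!all(vapply(object@rules, is, logical(1), "MarkerRule")))
        msg <- c(msg, "all rules must be MarkerRule objects")
    labs <- vapply(object@rules, function(r) r@label, character(1))
    if (anyDuplicated(labs))
        msg <- c(msg, "rule labels must be unique")
    if (!setequal(object@priority, labs) ||
        length(object@priority) != length(labs))
        msg <- c(msg, "priority must be a permutation of the rule labels")
    if (is.null(msg)) TRUE else msg
})

#' Construct a RuleSet
#'
#' @param rules list of [MarkerRule-class] objects.
#' @param priority label order used to resolve multi-rule matches; defaults
#'   to the order of `rules`.
#' @return a [RuleSet-class].
#' @export
ruleSet <- function(rules, priority = NULL) {
    labs <- vapply(rules, function(r) r@label, character(1))
    if (is.null(priority)) priority <- labs
    new("RuleSet", rules = rules, priority = priority)
}

#' @describeIn RuleSet-class labels of the housed rules, in priority order.
#' @param x a `RuleSet`.
#' @export
ruleLabels <- function(x) x@priority

#' @describeIn RuleSet-class all gene symbols referenced by any rule.
#' @export
ruleGenes <- function(x) unique(unlist(lapply(x@rules, function(r) r@genes)))

setMethod("show", "RuleSet", function(object) {
    cat("RuleSet with", length(object@rules), "rules\n")
    for (r in object@rules) {
        cl <- paste0(r@genes, ifelse(r@directions == "gt", " > ", " < "),
                     r@thresholds)
        cat(sprintf("  %-6s: %s\n", r@label, paste(cl, collapse = ", ")))
    }
    cat("priority:", paste(object@priority, collapse = " > "), "\n")
})

#' Pallial/subpallial lineage rule
#'
#' Disjoint transcription-factor panels and a shared normalized-log
#' threshold. A cell is pallial iff any pallial gene exceeds the threshold
#' while every subpallial gene stays below it; subpallial is the mirror
#' condition; a cell above threshold on both sides is "dual".
#'
#' @slot pallial pallial marker symbols.
#' @slot subpallial subpallial marker symbols (disjoint from pallial).
#' @slot threshold single positive threshold (default 0.25).
#' @export
setClass("LineageRule",
    representation(pallial = "character", subpallial = "character",
                   threshold = "numeric"))

setValidity("LineageRule", function(object) {
    msg <- NULL
    if (length(intersect(object@pallial, object@subpallial)))
        msg <- c(msg, "pallial and subpallial gene sets must be disjoint")
    if (length(object@threshold) != 1L || !is.finite(object@threshold) ||
        object@threshold <= 0)
        msg <- c(msg, "threshold must be a single positive number")
    if (!length(object@pallial) || !length(object@subpallial))
        msg <- c(msg, "both gene panels must be non-empty")
    if (is.null(msg)) TRUE else msg
})

#' Construct a LineageRule
#'
#' @param pallial,subpallial disjoint marker panels.
#' @param threshold normalized-log threshold (default 0.25).
#' @return a [LineageRule-class].
#' @export
lineageRule <- function(pallial, subpallial, threshold = 0.25) {
    new("LineageRule", pallial = as.character(pallial),
        subpallial = as.character(subpallial),
        threshold = as.numeric(threshold))
}

setMethod("show", "LineageRule", function(object) {
    cat("LineageRule (threshold", object@threshold, ")\n")
    cat("  pallial   :", paste(object@pallial, collapse = ", "), "\n")
    cat("  subpallial:", paste(object@subpallial, collapse = ", "), "\n")
})

#' Hopx stratification thresholds
#'
#' Strata of quiescent cells by normalized Hopx expression: high (> `high`),
#' low (< `low`), intermediate otherwise. Comparisons are strict.
#'
#' @slot gene gene symbol (default `"Hopx"`).
#' @slot high,low thresholds with `low < high`.
#' @export
setClass("HopxStrata",
    representation(gene = "character", high = "numeric", low = "numeric"))

setValidity("HopxStrata", function(object) {
    if (object@low >= object@high) "low threshold must be < high threshold"
    else TRUE
})

#' Construct HopxStrata thresholds
#'
#' Defaults follow the published definition: high = Hopx > 2.5,
#' low = Hopx < 0.4 on the normalized-log scale.
#'
#' @param gene gene symbol.
#' @param high,low strict thresholds.
#' @return a [HopxStrata-class].
#' @export
hopxStrata <- function(gene = "Hopx", high = 2.5, low = 0.4) {
    new("HopxStrata", gene = gene, high = high, low = low)
}

#' Configuration of the synthetic UMI count generator
#'
#' Holds the study conditions emulated by [simulateCounts()]: cell-type mix,
#' lineage and quiescence structure, QC violators, doublets, and the
#' negative-binomial/log-normal noise model. See the methods vignette for
#' the rationale behind each default.
#'
#' @slot n_cells,n_genes matrix dimensions.
#' @slot type_proportions named fractions over cell types (sum to 1).
#' @slot lineage_rate fraction of cells (outside TAP/NB) carrying a lineage
#'   program.
#' @slot pallial_fraction fraction of lineage-bearing cells given pallial
#'   programs.
#' @slot dual_rate fraction of lineage-bearing cells given both programs.
#' @slot doublet_rate fraction of barcodes replaced by sums of two cells.
#' @slot mito_gene_count number of `mt-` prefixed genes.
#' @slot mito_mean_fraction expected mitochondrial count fraction.
#' @slot high_mito_rate,lowgene_rate,highgene_rate fractions of planted QC
#'   violators.
#' @slot nb_dispersion,marker_dispersion NB size parameters for background
#'   and marker genes.
#' @slot libsize_meanlog,libsize_sdlog log-normal library-size model.
#' @slot hopx_high_rate fraction of qNSCs planted Hopx-high (deep quiescent).
#' @slot deep_detected_factor background scaling for deep-quiescent cells
#'   (drives the reduced detected-genes phenotype).
#' @slot s_rate,g2m_rate cycling-phase rates among proliferative types.
#' @slot margin,on_floor,on_cap marker-program placement on the
#'   normalized-log scale (see [buildMarkerPrograms()]).
#' @slot scale_factor normalization scale factor the thresholds assume.
#' @slot seed integer seed governing the whole simulation.
#' @export
setClass("SimConfig",
    representation(
        n_cells = "integer", n_genes = "integer",
        type_proportions = "numeric",
        lineage_rate = "numeric", pallial_fraction = "numeric",
        dual_rate = "numeric", doublet_rate = "numeric",
        mito_gene_count = "integer", mito_mean_fraction = "numeric",
        high_mito_rate = "numeric", lowgene_rate = "numeric",
        highgene_rate = "numeric",
        nb_dispersion = "numeric", marker_dispersion = "numeric",
        libsize_meanlog = "numeric", libsize_sdlog = "numeric",
        hopx_high_rate = "numeric", deep_detected_factor = "numeric",
        s_rate = "numeric", g2m_rate = "numeric",
        margin = "numeric", on_floor = "numeric", on_cap = "numeric",
        scale_factor = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- NULL
    p <- object@type_proportions
    if (abs(sum(p) - 1) > 1e-9)
        msg <- c(msg, "type_proportions must sum to 1 (+/- 1e-9)")
    if (is.null(names(p)) || anyDuplicated(names(p)))
        msg <- c(msg, "type_proportions must have unique names")
    rates <- c(object@lineage_rate, object@pallial_fraction, object@dual_rate,
               object@doublet_rate, object@mito_mean_fraction,
               object@high_mito_rate, object@lowgene_rate,
               object@highgene_rate, object@hopx_high_rate,
               object@deep_detected_factor, object@s_rate, object@g2m_rate)
    if (any(rates < 0) || any(rates > 1))
        msg <- c(msg, "all rates/fractions must lie in [0, 1]")
    if (object@nb_dispersion <= 0 || object@marker_dispersion <= 0)
        msg <- c(msg, "dispersions must be > 0")
    if (object@margin <= 0)
        msg <- c(msg, "margin must be > 0")
    if (object@highgene_rate > 0 && object@n_genes <= 7500L)
        msg <- c(msg,
            "highgene_rate > 0 is infeasible: cells cannot exceed 7500 detected genes with n_genes <= 7500")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@n_cells, "cells x", object@n_genes, "genes,",
        "seed", object@seed, "\n")
    cat("  types:", paste(sprintf("%s=%.3f", names(object@type_proportions),
        object@type_proportions), collapse = " "), "\n")
    cat(sprintf("  lineage %.2f (pallial %.2f, dual %.3f), doublets %.3f\n",
        object@lineage_rate, object@pallial_fraction, object@dual_rate,
        object@doublet_rate))
    cat(sprintf("  QC violators: mito %.3f, low-genes %.3f, high-genes %.3f\n",
        object@high_mito_rate, object@lowgene_rate, object@highgene_rate))
})
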