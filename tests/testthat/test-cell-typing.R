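norm_fixture <- function(values) {
    # values: named list barcode -> named numeric gene vector
    genes <- unique(unlist(lapply(values, names)))
    m <- matrix(0, length(genes), length(values),
                dimnames = list(genes, names(values)))
    for (b in names(values)) m[names(values[[b]]), b] <- values[[b]]
    m
}

rule_genes_zero <- function() {
    setNames(numeric(length(ruleGenes(defaultRuleSet()))),
             ruleGenes(defaultRuleSet()))
}

test_that("the printed rules classify forced cells as printed", {
    base <- rule_genes_zero()
    qn <- base; qn[c("Slc1a3", "Prom1")] <- c(2, 1)
    an <- base; an[c("Egfr", "Ascl1", "Dlx1", "Dlx2")] <-
        c(1.5, 1.5, 0.005, 0.005)
    tap <- base; tap[c("Egfr", "Ascl1", "Dlx1", "Dlx2")] <-
        c(1.5, 1.5, 0.02, 0.02)
    m <- norm_fixture(list(q = qn, a = an, t = tap, zero = base))
    res <- classifyCellTypes(m)
    expect_identical(as.character(res$cell_type),
                     c("qNSC", "aNSC", "TAP", "unassigned"))
    expect_false(any(res$type_ambiguous))
})

test_that("a missing rule gene is an error naming the symbols, never a zero", {
    m <- matrix(1, 2, 1, dimnames = list(c("Slc1a3", "Prom1"), "c1"))
    expect_error(classifyCellTypes(m), "Egfr")
})

test_that("multi-rule matches resolve by priority and are flagged", {
    rs <- ruleSet(list(
        markerRule("A", "g1", "gt", 0.5),
        markerRule("B", "g1", "gt", 0.2)), priority = c("B", "A"))
    m <- matrix(c(1, 0.3, 0), 3, 1, dimnames = list(NULL, "c1"))
    m <- matrix(c(1), 1, 1, dimnames = list("g1", "c1"))
    res <- classifyCellTypes(m, rs)
    expect_identical(as.character(res$cell_type), "B")
    expect_true(res$type_ambiguous)
    expect_equal(res$n_rules_matched, 2L)
})

test_that("relaxing an exclusion threshold can only grow the matched set", {
    set.seed(42)
    genes <- ruleGenes(defaultRuleSet())
    m <- matrix(runif(length(genes) * 200, 0, 3), length(genes), 200,
                dimnames = list(genes, paste0("c", 1:200)))
    strict <- defaultRuleSet()
    relaxed <- defaultRuleSet()
    # qNSC rule: Egfr < 0.1 -> Egfr < 0.2
    idx <- which(vapply(relaxed@rules, function(r) r@label, "") == "qNSC")
    relaxed@rules[[idx]]@thresholds[3] <- 0.2
    s1 <- classifyCellTypes(m, strict)$cell_type == "qNSC"
    s2 <- classifyCellTypes(m, relaxed)$cell_type == "qNSC"
    expect_true(all(which(s1) %in% which(s2)))
})

test_that("classification and lineage are permutation equivariant", {
    set.seed(7)
    genes <- unique(c(ruleGenes(defaultRuleSet()),
                      defaultLineageRule()@pallial,
                      defaultLineageRule()@subpallial))
    m <- matrix(runif(length(genes) * 50, 0, 3), length(genes), 50,
                dimnames = list(genes, paste0("c", 1:50)))
    perm <- sample(50)
    expect_identical(
        as.character(classifyCellTypes(m)$cell_type)[perm],
        as.character(classifyCellTypes(m[, perm])$cell_type))
    expect_identical(as.character(assignLineage(m))[perm],
                     as.character(assignLineage(m[, perm])))
})

test_that("lineage assignment follows the printed panel logic, strictly", {
    lr <- defaultLineageRule()
    genes <- c(lr@pallial, lr@subpallial)
    mk <- function(...) {
        v <- setNames(numeric(length(genes)), genes)
        args <- list(...)
        v[names(args)] <- unlist(args)
        v
    }
    m <- norm_fixture(list(
        p = mk(Emx1 = 0.3),
        d = mk(Emx1 = 0.3, Gsx2 = 0.3),
        s = mk(Gsx2 = 0.3),
        na = mk(),
        boundary = mk(Emx1 = 0.3, Gsx2 = 0.25)))  # 0.25 satisfies neither
    lin <- assignLineage(m, lr)
    expect_identical(as.character(lin),
                     c("pallial", "dual", "subpallial", "not_applicable",
                       "not_applicable"))
    # the four categories partition every cell
    expect_false(anyNA(lin))
})

test_that("Hopx strata use strict thresholds and report exact counts", {
    m <- matrix(c(3, 0.1, 1, 2.5, 0.4), 1, 5,
                dimnames = list("Hopx", paste0("c", 1:5)))
    st <- stratifyHopx(m)
    expect_identical(as.character(st$stratum),
                     c("high", "low", "intermediate", "intermediate",
                       "intermediate"))
    expect_equal(as.vector(st$counts), c(1L, 1L, 3L))
    sub <- stratifyHopx(m, cells = c("c1", "c2"))
    expect_equal(as.vector(sub$counts), c(1L, 1L, 0L))
    expect_error(stratifyHopx(m, cells = integer(0)), "empty")
    m2 <- matrix(1, 1, 1, dimnames = list("Other", "c1"))
    expect_error(stratifyHopx(m2), "Hopx")
})

test_that("RNA-content check separates planted doublets from true duals", {
    set.seed(9)
    singles <- matrix(rpois(40 * 20, 5), 40, 20,
                      dimnames = list(paste0("g", 1:40), paste0("s", 1:20)))
    # duals that are exact duplicates of singles: ratio 1, no rejection
    dup <- singles[, 1:10]
    colnames(dup) <- paste0("d", 1:10)
    m <- cbind(singles, dup)
    lin <- c(rep("pallial", 20), rep("dual", 10))
    rc <- rnaContentCheck(m, lin)
    expect_equal(rc$ratio, 1, tolerance = 0.1)
    expect_gt(rc$p_value, 0.05)
    # duals that are pairwise sums (planted doublets): ratio ~ 2
    sums <- singles[, 1:10] + singles[, 11:20]
    colnames(sums) <- paste0("d", 1:10)
    rc2 <- rnaContentCheck(cbind(singles, sums), lin)
    expect_equal(rc2$ratio, 2, tolerance = 0.15)
    expect_lt(rc2$p_value, 0.01)
    # a single dual cell cannot be tested
    rc3 <- rnaContentCheck(cbind(singles, sums[, 1, drop = FALSE]),
                           c(rep("pallial", 20), "dual"))
    expect_false(rc3$valid)
    expect_true(is.na(rc3$p_value))
})

test_that("composition tables count, renormalize and order deterministically", {
    ann <- data.frame(
        cell_type = c(rep("qNSC", 6), rep("TAP", 2), "NB", "OL"),
        lineage = c(rep("pallial", 6), rep("subpallial", 4)))
    # all-qNSC group: single row with fraction 1 once NB/OL are excluded
    comp <- computeComposition(ann, "lineage")
    pal <- comp[comp$group == "pallial" & comp$count > 0, ]
    expect_equal(nrow(pal), 1)
    expect_equal(pal$fraction, 1)
    # exclusion renormalizes the remaining types
    sub <- comp[comp$group == "subpallial" & comp$count > 0, ]
    expect_identical(sub$cell_type, "TAP")
    expect_equal(sub$fraction, 1)
    full <- computeComposition(ann, "lineage", exclude_types = character(0))
    sub_full <- full[full$group == "subpallial" & full$count > 0, ]
    expect_equal(sum(sub_full$fraction), 1, tolerance = 1e-9)
    expect_equal(sort(sub_full$cell_type), c("NB", "OL", "TAP"))
    expect_error(computeComposition(ann, "sample"), "unknown group_by")
    # fractions sum to 1 within every group
    agg <- tapply(full$fraction, full$group, sum)
    expect_true(all(abs(agg - 1) < 1e-9))
})
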