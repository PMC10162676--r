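test_that("complete separation at 6 vs 6 gives the exact enumeration p-value", {
    fx <- makeFixture("two_groups_de")
    norm <- normalizeLog(fx)
    res <- wilcoxonDE(norm, fx$group == "g1", fx$group == "g2")
    de <- res[res$gene == "DEgene01", ]
    expect_equal(de$p_val, 2 / choose(12, 6), tolerance = 1e-12)
    expect_gt(de$avg_logFC, 0.25)
    expect_gte(de$pct.1, 0.25)
    expect_true(de$enriched)
    expect_equal(de$p_adj, min(1, de$p_val * nrow(norm)), tolerance = 1e-12)
})

test_that("exact rank-sum p matches full enumeration for all small tie-free designs", {
    set.seed(21)
    for (n1 in 2:6) for (n2 in 2:(12 - n1)) {
        x <- sample(1000, n1) / 7
        y <- sample(1000, n2) / 7
        if (anyDuplicated(c(x, y))) next
        expect_equal(svztyper:::.rankSumP(x, y), oracle_ranksum_p(x, y),
                     tolerance = 1e-12,
                     info = sprintf("n1=%d n2=%d", n1, n2))
    }
    # complete separation closed form at a few sizes
    for (n in c(3, 5, 6)) {
        x <- seq_len(n) + 100
        y <- seq_len(n)
        expect_equal(svztyper:::.rankSumP(x, y), 2 / choose(2 * n, n),
                     tolerance = 1e-12)
    }
})

test_that("group swap negates the fold change, swaps detection, keeps p", {
    sim <- simulateTwoGroups(n_per = 25, n_genes = 150, n_de = 10,
                             fold = 2, seed = 8)
    norm <- normalizeLog(sim)
    p <- deParams(min_pct = 0, logfc_threshold = 0)
    a <- wilcoxonDE(norm, sim$group == "g1", sim$group == "g2", p)
    b <- wilcoxonDE(norm, sim$group == "g2", sim$group == "g1", p)
    b <- b[match(a$gene, b$gene), ]
    expect_equal(a$avg_logFC, -b$avg_logFC, tolerance = 1e-12)
    expect_equal(a$pct.1, b$pct.2, tolerance = 1e-12)
    expect_equal(a$p_val, b$p_val, tolerance = 1e-12)
})

test_that("pre-filters drop flat and barely-detected genes before testing", {
    # one gene identically distributed (logFC 0), one detected in 5% of
    # both groups, one clear marker
    set.seed(2)
    m <- matrix(0L, 4, 40,
                dimnames = list(c("flat", "rare", "marker", "ballast"),
                                sprintf("c%02d", 1:40)))
    m["flat", ] <- 5L
    m["rare", c(1, 21)] <- 1L                 # 5% of each group of 20
    m["marker", 1:20] <- 10L
    m["marker", 21:40] <- 1L
    m["ballast", 1:20] <- 1L                  # equalizes library sizes
    m["ballast", 21:40] <- 10L
    norm <- normalizeLog(m)
    res <- wilcoxonDE(norm, 1:20, 21:40)
    expect_false("flat" %in% res$gene)        # fails the logFC filter
    expect_false("rare" %in% res$gene)        # fails min.pct
    expect_true("marker" %in% res$gene)
    expect_error(wilcoxonDE(norm, 1:20, 15:40), "disjoint")
})

test_that("Bonferroni adjustment follows the printed cap rule", {
    expect_equal(bonferroniAdjust(0.001, 20000), 1.0)
    expect_equal(bonferroniAdjust(1e-6, 10000), 0.01)
    expect_equal(bonferroniAdjust(0, 5), 0)
    # order preserving and idempotent at the cap
    p <- c(1e-8, 1e-4, 0.2)
    adj <- bonferroniAdjust(p, 1000)
    expect_identical(order(adj), order(p))
    expect_equal(bonferroniAdjust(adj, 1000)[3], 1)
    expect_error(bonferroniAdjust(1.2, 10), "\\[0, 1\\]")
    expect_error(bonferroniAdjust(c(0.1, 0.2), 1), ">=")
})

test_that("the enrichment filter applies all three published clauses", {
    res <- data.frame(
        gene = c("in", "lowpct", "lowfc", "highp"),
        p_val = c(0.04, 0.04, 0.04, 0.06),
        p_adj = c(1, 1, 1, 1),
        avg_logFC = c(0.3, 0.3, 0.2, 0.3),
        pct.1 = c(0.30, 0.20, 0.30, 0.30),
        pct.2 = c(0.1, 0.1, 0.1, 0.1))
    expect_identical(filterEnriched(res), "in")
    expect_identical(filterEnriched(res, use_adjusted = TRUE), character(0))
})

test_that("TF/TR flags match hand-counted memberships on a 10-gene fixture", {
    sets <- list(dna = c("A", "B", "C", "D"), tr = c("C", "D", "E", "F"))
    genes <- c(LETTERS[1:8], "X", "Y")
    res <- annotateTfTr(genes, sets)
    expect_equal(sum(res$is_tf_tr), 6)                 # union A..F
    expect_equal(sum(res$dna & res$tr), 2)             # C, D
    expect_equal(sum(res$dna & !res$tr), 2)            # A, B
    expect_false(any(res$is_tf_tr[res$gene %in% c("X", "Y")]))
    expect_error(annotateTfTr(genes, list()), "at least one")
    # packaged synthetic subsets load and flag a known TF
    pk <- annotateTfTr(c("Sox2", "Gene00001"))
    expect_true(pk$is_tf_tr[1])
    expect_false(pk$is_tf_tr[2])
})

test_that("detected-genes summary reports means and oriented percent difference", {
    m <- matrix(0L, 5, 4, dimnames = list(paste0("g", 1:5),
                                          paste0("c", 1:4)))
    m[1:2, 1] <- 1L; m[1:3, 2] <- 1L; m[1:4, 3] <- 1L; m[1:2, 4] <- 1L
    s <- detectedGenesSummary(m, list(A = c("c1", "c2"), B = c("c3")))
    expect_equal(unname(s$means), c(2.5, 4))
    expect_equal(s$percent_difference, (1 - 2.5 / 4) * 100)
    expect_match(s$comparison, "A relative to B")
    same <- detectedGenesSummary(m, list(A = "c1", B = "c4"))
    expect_equal(same$percent_difference, 0)   # identical groups
    expect_equal(unname(same$means[1]), 2)     # single-cell group
})

test_that("deep-quiescent cells show the planted reduced gene detection", {
    cfg <- simConfig(n_cells = 500, n_genes = 6000,
                     deep_detected_factor = 0.5, seed = 9)
    sim <- simulateCounts(cfg)
    truth <- SummarizedExperiment::colData(sim)
    ok <- !truth$is_doublet & truth$qc_violation == "none" &
        truth$true_type == "qNSC"
    deep <- colnames(sim)[ok & truth$true_hopx_stratum == "high"]
    shallow <- colnames(sim)[ok & truth$true_hopx_stratum == "low"]
    s <- detectedGenesSummary(sim, list(deep = deep, shallow = shallow))
    expect_gt(s$percent_difference, 8)
    expect_lt(s$percent_difference, 16)
})
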