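test_that("marker programs straddle the thresholds per the +/- margin formula", {
    pr <- buildMarkerPrograms(defaultRuleSet(), defaultLineageRule(),
                              margin = 0.5)
    slc <- pr[pr$source == "qNSC" & pr$gene == "Slc1a3", ]
    expect_equal(slc$on_mean, 1.5)
    expect_equal(slc$off_mean, 0.5)
    # exclusion vs inclusion of the same gene in different rules
    expect_equal(pr[pr$source == "qNSC" & pr$gene == "Egfr", "off_mean"],
                 0.05)
    expect_equal(pr[pr$source == "aNSC" & pr$gene == "Egfr", "on_mean"],
                 1.5)
    expect_error(buildMarkerPrograms(defaultRuleSet(), defaultLineageRule(),
                                     margin = 0), "margin")
    # with the generator's floor/cap, every program still separates
    pr2 <- buildMarkerPrograms(defaultRuleSet(), defaultLineageRule(),
                               margin = 2, on_floor = 3, on_cap = 4)
    expect_true(all(pr2$on_mean > pr2$threshold))
    expect_true(all(pr2$off_mean < pr2$threshold))
    expect_true(all(pr2$off_mean >= 0))
})

test_that("simulation is bit-identical under a fixed seed", {
    cfg <- simConfig(n_cells = 120, n_genes = 2000,
                     type_proportions = testProportions(), seed = 77)
    s1 <- simulateCounts(cfg)
    s2 <- simulateCounts(cfg)
    expect_identical(as.matrix(SummarizedExperiment::assay(s1)),
                     as.matrix(SummarizedExperiment::assay(s2)))
    expect_identical(as.data.frame(SummarizedExperiment::colData(s1)),
                     as.data.frame(SummarizedExperiment::colData(s2)))
})

test_that("planted high-mito cells realize their violation and only theirs", {
    cfg <- simConfig(n_cells = 600, n_genes = 2000,
                     type_proportions = testProportions(),
                     high_mito_rate = 0.1, lowgene_rate = 0,
                     doublet_rate = 0, seed = 13)
    sim <- simulateCounts(cfg)
    truth <- SummarizedExperiment::colData(sim)
    qc <- qcFilterCells(sim, min_genes = 0, max_genes = 1e9)
    flagged <- qc$report$mito_fraction > 0.10
    expect_equal(sum(truth$qc_violation == "high_mito"), 60)
    expect_true(all(flagged[truth$qc_violation == "high_mito"]))
    # ~60/600 above the threshold overall (planting is exact; clean cells
    # sit far below 0.10, so the count matches the planted 10%)
    expect_true(sum(flagged) >= 60 && sum(flagged) <= 66)
})

test_that("dual_rate 0 plants no dual cells", {
    cfg <- simConfig(n_cells = 150, n_genes = 2000,
                     type_proportions = testProportions(),
                     dual_rate = 0, seed = 5)
    sim <- simulateCounts(cfg)
    expect_false(any(SummarizedExperiment::colData(sim)$true_lineage ==
                     "dual"))
})

test_that("empirical type proportions among clean cells sit in the 99% binomial band", {
    cfg <- simConfig(n_cells = 1500, seed = 202)
    sim <- simulateCounts(cfg)
    truth <- SummarizedExperiment::colData(sim)
    clean <- !truth$is_doublet & truth$qc_violation == "none"
    tab <- table(truth$true_type[clean]) / sum(clean)
    for (tp in names(cfg@type_proportions)) {
        band <- binom99(sum(clean), cfg@type_proportions[[tp]])
        expect_gte(tab[[tp]], band[1])
        expect_lte(tab[[tp]], band[2])
    }
})

test_that("the generator is calibrated: clean cells pass their intended rule", {
    cfg <- simConfig(n_cells = 1500, seed = 202)
    sim <- simulateCounts(cfg)
    truth <- SummarizedExperiment::colData(sim)
    norm <- normalizeLog(qcFilterCells(filterGenesMinCells(sim))$sce)
    truth <- truth[colnames(norm), ]
    typing <- classifyCellTypes(norm)
    clean <- !truth$is_doublet & truth$qc_violation == "none" &
        as.character(truth$true_type) %in%
            c("qNSC", "aNSC", "TAP", "NB", "OL", "Astro")
    hit <- as.character(typing$cell_type[clean]) ==
        as.character(truth$true_type[clean])
    expect_gte(mean(hit), 0.99)
    # QC removed exactly the planted violators
    rep <- qcFilterCells(filterGenesMinCells(sim))$report
    full_truth <- SummarizedExperiment::colData(sim)
    expect_identical(unname(!rep$pass),
                     as.vector(full_truth$qc_violation != "none"))
})

test_that("planted Hopx strata land on the right side of 2.5 / 0.4", {
    cfg <- simConfig(n_cells = 1000, seed = 31)
    sim <- simulateCounts(cfg)
    truth <- SummarizedExperiment::colData(sim)
    norm <- normalizeLog(qcFilterCells(filterGenesMinCells(sim))$sce)
    truth <- truth[colnames(norm), ]
    qn <- truth$true_type == "qNSC" & !truth$is_doublet &
        truth$qc_violation == "none"
    hopx <- as.numeric(
        SummarizedExperiment::assay(norm, "logcounts")["Hopx", qn])
    planted <- as.character(truth$true_hopx_stratum[qn])
    expect_gte(mean(hopx[planted == "high"] > 2.5), 0.95)
    expect_gte(mean(hopx[planted == "low"] < 0.4), 0.95)
})

test_that("infeasible and inconsistent configurations are rejected", {
    expect_error(simConfig(n_genes = 3000, highgene_rate = 0.05),
                 "infeasible")
    expect_error(simConfig(type_proportions = c(a = 0.5, b = 0.4)),
                 "sum to 1")
    expect_error(simConfig(dual_rate = 1.5), "\\[0, 1\\]")
    expect_error(
        simulateCounts(simConfig(n_cells = 10, n_genes = 100,
                                 type_proportions = testProportions())),
        "n_genes must exceed")
})

test_that("hand-specified fixtures match their documented construction", {
    tq <- makeFixture("tiny_qc")
    expect_identical(dim(tq), c(7600L, 10L))
    expect_equal(sum(SummarizedExperiment::colData(tq)$qc_violation !=
                     "none"), 3)

    de <- makeFixture("two_groups_de")
    m <- SummarizedExperiment::assay(de)
    g1 <- de$group == "g1"
    expect_true(min(m["DEgene01", g1]) > max(m["DEgene01", !g1]))
    expect_false(anyDuplicated(m["DEgene01", ]) > 0)

    ra <- makeFixture("ranked_auc")
    expect_identical(as.integer(SummarizedExperiment::assay(ra)[, 1]),
                     20:1)

    cd <- makeFixture("cycle_demo")
    truth <- SummarizedExperiment::colData(cd)$true_phase
    cyc_rows <- seq_len(30)
    expect_true(all(SummarizedExperiment::assay(cd)[cyc_rows,
                    truth == "G1_G0"] == 0))
    expect_error(makeFixture("nope"))
})

test_that("doublets are sums of two cells and inflate RNA content twofold", {
    cfg <- simConfig(n_cells = 500, n_genes = 2000,
                     type_proportions = testProportions(),
                     doublet_rate = 0.05, seed = 19)
    sim <- simulateCounts(cfg)
    truth <- SummarizedExperiment::colData(sim)
    tot <- Matrix::colSums(SummarizedExperiment::assay(sim))
    ratio <- mean(tot[truth$is_doublet]) / mean(tot[!truth$is_doublet])
    expect_gt(ratio, 1.7)
    expect_lt(ratio, 2.3)
})
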