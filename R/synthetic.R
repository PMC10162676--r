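#' Construct a synthetic-data generator configuration
#'
#' Defaults encode the study conditions the generator emulates: the
#' published cell-type composition (52/17/17% for qNSC/aNSC/TAP, 6.6% EC,
#' 5.4% Astro, 1% OL, 0.5% NB, plus 0.5% unruled "other" cells closing the
#' simplex), a majority-pallial lineage mix, a roughly even Hopx-high/low
#' split among qNSCs, small planted QC-violator and doublet fractions, and
#' a negative-binomial count model with log-normal library sizes (about
#' 20,000 UMIs per cell, matching high-coverage 10x data). See the methods
#' vignette for the placement of marker programs relative to the
#' classifier thresholds.
#'
#' @param n_cells,n_genes matrix dimensions (defaults 5000 x 3000).
#' @param type_proportions named fractions summing to 1.
#' @param lineage_rate fraction of cells (TAP/NB are always
#'   subpallial-lineage-bearing) carrying a lineage program.
#' @param pallial_fraction pallial share of lineage-bearing cells.
#' @param dual_rate fraction of lineage-bearing cells given both programs.
#' @param doublet_rate fraction of barcodes that are sums of two cells.
#' @param mito_gene_count number of `mt-` genes (default 13, the mouse
#'   mtDNA protein genes).
#' @param mito_mean_fraction expected mitochondrial fraction (default 0.05).
#' @param high_mito_rate,lowgene_rate,highgene_rate planted QC-violator
#'   fractions (`highgene_rate > 0` requires `n_genes > 7500`).
#' @param nb_dispersion,marker_dispersion NB size for background and marker
#'   genes.
#' @param libsize_meanlog,libsize_sdlog library-size log-normal model.
#' @param hopx_high_rate Hopx-high (deep-quiescent) fraction of qNSCs.
#' @param deep_detected_factor scaling of baseline expression in
#'   deep-quiescent cells, driving their reduced detected-genes phenotype.
#' @param s_rate,g2m_rate cycling rates among proliferative types
#'   (aNSC/TAP/NB).
#' @param margin,on_floor,on_cap marker-program placement (normalized-log
#'   scale); see [buildMarkerPrograms()].
#' @param scale_factor normalization scale factor the thresholds assume.
#' @param seed integer seed; one seed governs the whole simulation.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(n_cells = 5000, n_genes = 3000,
                      type_proportions = c(qNSC = 0.52, aNSC = 0.17,
                                           TAP = 0.17, EC = 0.066,
                                           Astro = 0.054, OL = 0.01,
                                           NB = 0.005, other = 0.005),
                      lineage_rate = 0.56, pallial_fraction = 0.61,
                      dual_rate = 0.02, doublet_rate = 0.02,
                      mito_gene_count = 13, mito_mean_fraction = 0.05,
                      high_mito_rate = 0.01, lowgene_rate = 0.01,
                      highgene_rate = 0,
                      nb_dispersion = 10, marker_dispersion = 20,
                      libsize_meanlog = log(3e4), libsize_sdlog = 0.25,
                      hopx_high_rate = 0.53, deep_detected_factor = 0.7,
                      s_rate = 0.25, g2m_rate = 0.15,
                      margin = 2, on_floor = 3, on_cap = 4,
                      scale_factor = 1e4, seed = 1) {
    new("SimConfig", n_cells = as.integer(n_cells),
        n_genes = as.integer(n_genes),
        type_proportions = type_proportions,
        lineage_rate = lineage_rate, pallial_fraction = pallial_fraction,
        dual_rate = dual_rate, doublet_rate = doublet_rate,
        mito_gene_count = as.integer(mito_gene_count),
        mito_mean_fraction = mito_mean_fraction,
        high_mito_rate = high_mito_rate, lowgene_rate = lowgene_rate,
        highgene_rate = highgene_rate,
        nb_dispersion = nb_dispersion,
        marker_dispersion = marker_dispersion,
        libsize_meanlog = libsize_meanlog, libsize_sdlog = libsize_sdlog,
        hopx_high_rate = hopx_high_rate,
        deep_detected_factor = deep_detected_factor,
        s_rate = s_rate, g2m_rate = g2m_rate,
        margin = margin, on_floor = on_floor, on_cap = on_cap,
        scale_factor = scale_factor, seed = as.integer(seed))
}

# Normalized-log on-state target for a "greater" clause at threshold t:
# t * (1 + margin), floored and capped so the realized counts clear the
# threshold under NB noise without distorting the library budget.
.onMean <- function(t, margin, on_floor = 0, on_cap = Inf) {
    pmin(pmax(t * (1 + margin), on_floor), pmax(on_cap, t * (1 + 0.25)))
}

.offMean <- function(t, margin) pmax(t * (1 - margin), 0)

#' Derive marker on/off expression programs from classifier rules
#'
#' For every `(gene, threshold, direction)` clause of the cell-type rules
#' and the lineage panels, emits a program whose on/off normalized-log
#' means sit at `threshold * (1 +/- margin)` on the correct side of the
#' threshold (clipped below at 0 for the off state; optionally floored or
#' capped for the on state). The on-state mean is back-converted to a raw
#' UMI mean given the expected library size, so that post-normalization
#' expression lands near the target.
#'
#' @param rules a [RuleSet-class].
#' @param lineage_rule a [LineageRule-class].
#' @param margin relative margin (> 0); margin 0 or below is a
#'   configuration error.
#' @param on_floor,on_cap optional bounds on the on-state normalized-log
#'   mean (defaults 0 / Inf: the pure +/- margin formula).
#' @param expected_libsize,scale_factor back-conversion constants (both
#'   default 10000, making the raw mean `expm1(on_mean)`).
#' @return data.frame with columns `source` (rule label, `"pallial"` or
#'   `"subpallial"`), `gene`, `direction`, `threshold`, `on_mean`,
#'   `off_mean`, `raw_on_mean`.
#' @examples
#' head(buildMarkerPrograms(defaultRuleSet(), defaultLineageRule(), 0.5))
#' @export
buildMarkerPrograms <- function(rules, lineage_rule, margin,
                                on_floor = 0, on_cap = Inf,
                                expected_libsize = 1e4,
                                scale_factor = 1e4) {
    if (margin <= 0)
        stop("configuration error: margin must be > 0")
    rows <- list()
    for (r in rules@rules)
        rows[[length(rows) + 1L]] <- data.frame(
            source = r@label, gene = r@genes, direction = r@directions,
            threshold = r@thresholds)
    thr <- lineage_rule@threshold
    rows[[length(rows) + 1L]] <- data.frame(
        source = "pallial", gene = lineage_rule@pallial,
        direction = "gt", threshold = thr)
    rows[[length(rows) + 1L]] <- data.frame(
        source = "subpallial", gene = lineage_rule@subpallial,
        direction = "gt", threshold = thr)
    out <- do.call(rbind, rows)
    out$on_mean <- .onMean(out$threshold, margin, on_floor, on_cap)
    out$off_mean <- .offMean(out$threshold, margin)
    if (any(out$on_mean <= out$threshold) ||
        any(out$off_mean >= out$threshold) || any(out$on_mean <= 0))
        stop("configuration error: margin does not separate on/off means ",
             "from the thresholds")
    out$raw_on_mean <- expm1(out$on_mean) * expected_libsize / scale_factor
    rownames(out) <- NULL
    out
}

#' Simulate a UMI count matrix with planted ground truth
#'
#' Draws genes x cells UMI counts from a negative-binomial model with
#' log-normal cell size factors and program-dependent means. Marker
#' programs place each rule gene's expression on the correct side of its
#' classifier threshold (see [buildMarkerPrograms()]); lineage programs
#' activate the pallial or subpallial panel (both for dual cells), skipping
#' genes the cell's own type rule excludes; Hopx-high qNSCs additionally
#' receive the deep-quiescence signature, a globally reduced baseline
#' (fewer detected genes) and high Hopx; astrocytes receive the astrocytic
#' signature; cycling aNSC/TAP/NB cells receive the S or G2/M program.
#' Mitochondrial genes carry the `mt-` prefix. Planted QC violators
#' realize their violation after counting; doublets are sums of two
#' sampled cells' counts. The whole simulation is reproducible from the
#' config seed.
#'
#' @param config a [SimConfig-class].
#' @param rules RuleSet used for planting (default includes the optional
#'   EC rule, so ependymal cells express Foxj1).
#' @param lineage_rule,strata,signatures,cycle_genes structure being
#'   planted; defaults match the classifier defaults.
#' @return a `SingleCellExperiment` with a dense integer `counts` assay;
#'   `colData` holds the simulation truth (`true_type`, `true_lineage`,
#'   `true_hopx_stratum`, `true_phase`, `is_doublet`, `qc_violation`);
#'   `rowData$gene_class` distinguishes marker/mito/background genes;
#'   `metadata` keeps the config and program table.
#' @export
simulateCounts <- function(config, rules = defaultRuleSet(include_ec = TRUE),
                           lineage_rule = defaultLineageRule(),
                           strata = hopxStrata(),
                           signatures = signatureLibrary(),
                           cycle_genes = cellCycleGenes()) {
    methods::validObject(config)
    n <- config@n_cells
    B <- exp(config@libsize_meanlog)   # expected library size
    sf <- config@scale_factor
    programs <- buildMarkerPrograms(rules, lineage_rule, config@margin,
                                    config@on_floor, config@on_cap,
                                    expected_libsize = B, scale_factor = sf)
    onLevel <- function(target) expm1(target) * B / sf
    sig_on <- onLevel(config@on_floor)
    named <- unique(c(programs$gene, strata@gene, unlist(signatures),
                      unlist(cycle_genes)))
    mito <- .mitoGeneNames(config@mito_gene_count)
    n_bg <- config@n_genes - length(named) - length(mito)
    if (n_bg < 1)
        stop("configuration error: n_genes must exceed the number of named marker genes (",
             length(named), ") plus mito_gene_count")
    gene_names <- c(named, mito, sprintf("Gene%05d", seq_len(n_bg)))
    gene_class <- rep(c("marker", "mito", "background"),
                      c(length(named), length(mito), n_bg))

    .withSeed(config@seed, {
        ## --- baseline means (sum approximately B per cell) -------------
        marker_load <- 400   # typical on-program load, approximate
        bg_budget <- B * (1 - config@mito_mean_fraction) - marker_load
        bg_means <- rlnorm(n_bg, 0, 0.3)
        bg_means <- bg_means / sum(bg_means) * bg_budget
        mito_means <- rlnorm(length(mito), 0, 0.3)
        mito_means <- mito_means / sum(mito_means) *
            B * config@mito_mean_fraction
        # signature genes not referenced by any rule keep a background-
        # level baseline everywhere (they are broadly expressed genes)
        pure_sig <- setdiff(unlist(signatures),
                            c(programs$gene, strata@gene))
        base <- setNames(numeric(length(gene_names)), gene_names)
        base[gene_class == "background"] <- bg_means
        base[gene_class == "mito"] <- mito_means
        base[pure_sig] <- mean(bg_means)

        ## --- per-cell truth -------------------------------------------
        type_names <- names(config@type_proportions)
        type <- sample(type_names, n, TRUE, prob = config@type_proportions)
        forced_sub <- type %in% c("TAP", "NB")
        bearing <- forced_sub | (runif(n) < config@lineage_rate)
        side <- ifelse(forced_sub, "subpallial",
                       ifelse(runif(n) < config@pallial_fraction,
                              "pallial", "subpallial"))
        lin <- rep("not_applicable", n)
        lin[bearing] <- side[bearing]
        lin[bearing & runif(n) < config@dual_rate] <- "dual"
        hopx <- ifelse(type == "qNSC" & runif(n) < config@hopx_high_rate,
                       "high", "low")
        cycling <- type %in% c("aNSC", "TAP", "NB")
        ph_draw <- runif(n)
        phase <- ifelse(cycling & ph_draw < config@s_rate, "S",
                 ifelse(cycling & ph_draw < config@s_rate + config@g2m_rate,
                        "G2M", "G1_G0"))

        n_dbl <- round(config@doublet_rate * n)
        n_low <- round(config@lowgene_rate * n)
        n_high <- round(config@highgene_rate * n)
        n_hm <- round(config@high_mito_rate * n)
        special <- sample(n, n_dbl + n_low + n_high + n_hm)
        is_doublet <- logical(n)
        is_doublet[special[seq_len(n_dbl)]] <- TRUE
        viol <- rep("none", n)
        viol[special[n_dbl + seq_len(n_low)]] <- "low_genes"
        viol[special[n_dbl + n_low + seq_len(n_high)]] <- "high_genes"
        viol[special[n_dbl + n_low + n_high + seq_len(n_hm)]] <- "high_mito"

        ## --- mean matrix ----------------------------------------------
        mu <- matrix(base, length(gene_names), n,
                     dimnames = list(gene_names, NULL))
        deep <- type == "qNSC" & hopx == "high"
        mu[, deep] <- mu[, deep] * config@deep_detected_factor

        rule_labels <- vapply(rules@rules, function(r) r@label, character(1))
        lt_genes <- lapply(rules@rules, function(r)
            r@genes[r@directions == "lt"])
        names(lt_genes) <- rule_labels
        for (lab in intersect(rule_labels, unique(type))) {
            cells <- which(type == lab)
            pr <- programs[programs$source == lab &
                           programs$direction == "gt", ]
            if (nrow(pr)) mu[pr$gene, cells] <- rep(pr$raw_on_mean,
                                                    length(cells))
        }
        # GABAergic neuroblasts express Sp8/Gad2 (keeps genes that occur
        # only in exclusion clauses above the gene prevalence filter)
        nb_cells <- which(type == "NB")
        if (length(nb_cells))
            mu[intersect(c("Sp8", "Gad2"), gene_names), nb_cells] <-
                onLevel(config@on_floor)
        for (side_nm in c("pallial", "subpallial")) {
            panel <- programs[programs$source == side_nm, ]
            on_cells <- which(lin == side_nm | lin == "dual")
            for (lab in unique(type[on_cells])) {
                cells <- on_cells[type[on_cells] == lab]
                excl <- if (lab %in% names(lt_genes)) lt_genes[[lab]]
                        else character(0)
                pr <- panel[!(panel$gene %in% excl), ]
                if (nrow(pr)) mu[pr$gene, cells] <- rep(pr$raw_on_mean,
                                                        length(cells))
            }
        }
        hopx_hi_cells <- which(deep)
        if (length(hopx_hi_cells)) {
            mu[strata@gene, hopx_hi_cells] <-
                onLevel(.onMean(strata@high, config@margin,
                                config@on_floor, config@on_cap))
            dq <- intersect(signatures$deep_quiescence, gene_names)
            mu[dq, hopx_hi_cells] <- pmax(mu[dq, hopx_hi_cells], sig_on)
        }
        astro_cells <- which(type == "Astro")
        if (length(astro_cells) && !is.null(signatures$astro))
            mu[intersect(signatures$astro, gene_names), astro_cells] <-
                sig_on
        mu[intersect(cycle_genes$s, gene_names), phase == "S"] <- sig_on
        mu[intersect(cycle_genes$g2m, gene_names), phase == "G2M"] <- sig_on

        # planted QC violators (whole-cell scalings preserve the other
        # QC statistics, so each violator fails for exactly one reason)
        mu[, viol == "low_genes"] <- mu[, viol == "low_genes"] * 0.02
        mu[, viol == "high_genes"] <- mu[, viol == "high_genes"] * 5
        mf <- config@mito_mean_fraction
        mito_boost <- (0.25 * (1 - mf)) / (0.75 * mf)
        mu[gene_class == "mito", viol == "high_mito"] <-
            mu[gene_class == "mito", viol == "high_mito"] * mito_boost

        ## --- counts ----------------------------------------------------
        size_g <- ifelse(gene_class == "marker",
                         config@marker_dispersion, config@nb_dispersion)
        f <- rlnorm(n, 0, config@libsize_sdlog)
        mu <- sweep(mu, 2L, f, "*")
        counts <- matrix(rnbinom(length(mu), mu = mu, size = size_g),
                         nrow(mu), ncol(mu))
        storage.mode(counts) <- "integer"

        ## --- doublets: sums of two sampled singlet cells ---------------
        dbl <- which(is_doublet)
        if (length(dbl)) {
            singlets <- which(!is_doublet)
            p1 <- sample(singlets, length(dbl), replace = TRUE)
            p2 <- sample(singlets, length(dbl), replace = TRUE)
            counts[, dbl] <- counts[, p1] + counts[, p2]
            type[dbl] <- type[p1]; lin[dbl] <- lin[p1]
            hopx[dbl] <- hopx[p1]; phase[dbl] <- phase[p1]
            viol[dbl] <- "none"
        }

        barcodes <- sprintf("cell%05d", seq_len(n))
        dimnames(counts) <- list(gene_names, barcodes)
        truth <- S4Vectors::DataFrame(
            barcode = barcodes,
            true_type = factor(type, levels = type_names),
            true_lineage = factor(lin, levels = c("pallial", "subpallial",
                                                  "dual", "not_applicable")),
            true_hopx_stratum = factor(hopx, levels = c("high", "low",
                                                        "intermediate")),
            true_phase = factor(phase, levels = c("S", "G2M", "G1_G0")),
            is_doublet = is_doublet,
            qc_violation = factor(viol, levels = c("none", "low_genes",
                                                   "high_genes",
                                                   "high_mito")))
        rownames(truth) <- barcodes
        rd <- S4Vectors::DataFrame(symbol = gene_names,
                                   gene_class = gene_class)
        rownames(rd) <- gene_names
        SingleCellExperiment::SingleCellExperiment(
            assays = list(counts = counts), colData = truth, rowData = rd,
            metadata = list(config = config, programs = programs))
    })
}

#' Simulate two groups of cells with optional planted fold changes
#'
#' A deliberately simple two-condition NB model for testing differential
#' expression: gene baseline means are log-normal, the first `n_de` genes
#' get a `fold`-times higher mean in group 1 (baselines for these drawn
#' uniformly from an expressed range so the planted effect is detectable),
#' and both groups share the same library-size noise. With `n_de = 0` the
#' two groups are draws from the same distribution (a null model).
#'
#' @param n_per cells per group.
#' @param n_genes number of genes.
#' @param n_de number of planted differential genes (default 0).
#' @param fold mean fold change of planted genes in group 1 (default 2).
#' @param dispersion NB size (default 10).
#' @param seed seed.
#' @return a `SingleCellExperiment` with `counts`, `colData$group`
#'   (`"g1"`/`"g2"`) and `rowData$is_de`.
#' @export
simulateTwoGroups <- function(n_per = 100, n_genes = 2000, n_de = 0,
                              fold = 2, dispersion = 10, seed = NULL) {
    stopifnot(n_de <= n_genes)
    .withSeed(seed, {
        mu <- rlnorm(n_genes, log(2), 0.8)
        if (n_de > 0) mu[seq_len(n_de)] <- runif(n_de, 1, 5)
        mu1 <- mu
        if (n_de > 0) mu1[seq_len(n_de)] <- mu1[seq_len(n_de)] * fold
        n <- 2L * n_per
        f <- rlnorm(n, 0, 0.15)
        M <- cbind(matrix(mu1, n_genes, n_per), matrix(mu, n_genes, n_per))
        M <- sweep(M, 2L, f, "*")
        counts <- matrix(rnbinom(length(M), mu = M, size = dispersion),
                         n_genes, n)
        storage.mode(counts) <- "integer"
        genes <- sprintf("Gene%05d", seq_len(n_genes))
        barcodes <- sprintf("cell%04d", seq_len(n))
        dimnames(counts) <- list(genes, barcodes)
        SingleCellExperiment::SingleCellExperiment(
            assays = list(counts = counts),
            colData = S4Vectors::DataFrame(
                barcode = barcodes,
                group = factor(rep(c("g1", "g2"), each = n_per)),
                row.names = barcodes),
            rowData = S4Vectors::DataFrame(
                symbol = genes,
                is_de = seq_len(n_genes) <= n_de, row.names = genes))
    })
}
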