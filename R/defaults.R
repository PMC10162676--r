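#' Default marker-threshold rules for dorsal V-SVZ cell types
#'
#' The six published boolean rules on normalized log-counts:
#' \itemize{
#'   \item qNSC: Slc1a3 > 1, Prom1 > 0.6, Egfr < 0.1, Foxj1 < 0.1
#'   \item aNSC: Egfr > 1, Ascl1 > 1, Dlx1 < 0.01, Dlx2 < 0.01
#'   \item TAP: Egfr > 1, Ascl1 > 1, Dlx1 > 0.01, Dlx2 > 0.01,
#'     Sp8 < 0.5, Gad1 < 0.5, Gad2 < 0.5
#'   \item NB: Dcx > 1, Cd24a > 0.5, Nrxn3 > 0.5
#'   \item OL: Pdgfra > 0.5, Sox10 > 0.5
#'   \item Astro: S100b > 0.5, Aqp4 > 2
#' }
#' Tie-break priority is NB > TAP > aNSC > qNSC > OL > Astro, so the most
#' differentiated compatible identity wins; multi-rule matches are flagged
#' by [classifyCellTypes()].
#'
#' No rule is published for ependymal cells; `include_ec = TRUE` adds an
#' optional, non-default EC rule (Foxj1 > 0.5, lowest priority).
#'
#' @param include_ec add the optional ependymal rule.
#' @return a [RuleSet-class].
#' @examples
#' defaultRuleSet()
#' @export
defaultRuleSet <- function(include_ec = FALSE) {
    rules <- list(
        markerRule("qNSC", c("Slc1a3", "Prom1", "Egfr", "Foxj1"),
                   c("gt", "gt", "lt", "lt"), c(1, 0.6, 0.1, 0.1)),
        markerRule("aNSC", c("Egfr", "Ascl1", "Dlx1", "Dlx2"),
                   c("gt", "gt", "lt", "lt"), c(1, 1, 0.01, 0.01)),
        markerRule("TAP",
                   c("Egfr", "Ascl1", "Dlx1", "Dlx2", "Sp8", "Gad1", "Gad2"),
                   c("gt", "gt", "gt", "gt", "lt", "lt", "lt"),
                   c(1, 1, 0.01, 0.01, 0.5, 0.5, 0.5)),
        markerRule("NB", c("Dcx", "Cd24a", "Nrxn3"),
                   c("gt", "gt", "gt"), c(1, 0.5, 0.5)),
        markerRule("OL", c("Pdgfra", "Sox10"), c("gt", "gt"), c(0.5, 0.5)),
        markerRule("Astro", c("S100b", "Aqp4"), c("gt", "gt"), c(0.5, 2)))
    priority <- c("NB", "TAP", "aNSC", "qNSC", "OL", "Astro")
    if (include_ec) {
        rules <- c(rules, markerRule("EC", "Foxj1", "gt", 0.5))
        priority <- c(priority, "EC")
    }
    ruleSet(rules, priority)
}

#' Default pallial/subpallial lineage rule
#'
#' Pallial panel Emx1, Neurod1, Neurod6, Neurog2, Tbr1; subpallial panel
#' Gsx2, Dlx6, Dlx5, Sp9, Dlx2, Gad1; shared threshold 0.25 on the
#' normalized-log scale, strict comparisons as published.
#'
#' @return a [LineageRule-class].
#' @export
defaultLineageRule <- function() {
    lineageRule(
        pallial = c("Emx1", "Neurod1", "Neurod6", "Neurog2", "Tbr1"),
        subpallial = c("Gsx2", "Dlx6", "Dlx5", "Sp9", "Dlx2", "Gad1"),
        threshold = 0.25)
}

#' Published AUC signature gene lists
#'
#' The 10-gene astrocytic signature and the 11-gene deep-quiescence
#' signature scored per cell by [scoreSignatures()].
#'
#' @return named list with elements `astro` and `deep_quiescence`.
#' @export
signatureLibrary <- function() {
    list(
        astro = c("Fam107a", "Cbs", "Mlc1", "Ntsr2", "Clu", "Ppp1r3g",
                  "Gm11627", "Mfge8", "Cldn10", "S1pr1"),
        deep_quiescence = c("Notch2", "Foxg1", "Prom1", "Id1", "Foxo3",
                            "Sox2", "Sox9", "Pdgfra", "Nr2e1", "Ascl1",
                            "Nfix"))
}

#' Default mouse cell-cycle gene lists
#'
#' Standard S-phase and G2/M marker lists (mouse symbols), shipped as a GMT
#' fixture and used by [scoreCellCycle()] unless the caller supplies their
#' own sets.
#'
#' @return named list with elements `s` and `g2m`.
#' @export
cellCycleGenes <- function() {
    path <- system.file("extdata", "cell_cycle_mouse.gmt",
                        package = "svztyper", mustWork = TRUE)
    sets <- readGeneSets(path)
    list(s = sets[["S_phase"]], g2m = sets[["G2M_phase"]])
}

# Mouse mitochondrial protein-coding gene symbols (mt- prefix keys QC).
.mitoGeneNames <- function(n = 13L) {
    base <- c("mt-Nd1", "mt-Nd2", "mt-Co1", "mt-Co2", "mt-Atp8", "mt-Atp6",
              "mt-Co3", "mt-Nd3", "mt-Nd4l", "mt-Nd4", "mt-Nd5", "mt-Nd6",
              "mt-Cytb")
    if (n <= length(base)) base[seq_len(n)]
    else c(base, sprintf("mt-Gene%d", seq_len(n - length(base))))
}
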