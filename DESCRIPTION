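Package: svztyper
Title: Threshold-Rule Cell Typing and Quiescence Scoring for Dorsal V-SVZ
    Single-Cell RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rule-based annotation of mouse ventricular-subventricular zone
    (V-SVZ) single-cell RNA-seq data. Implements quality-control filtering on
    detected genes and mitochondrial fraction, library-size log-normalization,
    boolean marker-threshold classification of neural stem cell states (qNSC,
    aNSC, TAP, NB, OL, Astro), pallial/subpallial/dual lineage assignment,
    Hopx-based quiescence stratification, expression-bin-matched cell-cycle
    scoring, rank-based AUC gene-signature scoring (astrocytic and deep
    quiescence signatures), and Wilcoxon rank-sum differential expression with
    Bonferroni correction. A negative-binomial UMI count simulator with
    planted ground truth makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
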