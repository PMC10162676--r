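---
title: "Threshold-rule annotation of dorsal V-SVZ scRNA-seq: models, parameters and design"
author: "svztyper authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-rule annotation of dorsal V-SVZ scRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svztyper)
```

## The problem and the approach

The dorsal wall of the postnatal ventricular–subventricular zone (V-SVZ)
hosts neural stem cells (NSCs) of two embryonic origins. Pallial NSCs
silence their glutamatergic output shortly after birth by entering deep
quiescence — high BMP signalling, high `Hopx`, reduced transcription —
while subpallial NSCs stay primed for GABAergic neurogenesis. `svztyper`
annotates single-cell UMI matrices from this niche with *explicit
threshold rules on normalized expression* rather than clustering: every
call is a deterministic function of a cell's expression vector, so the
annotation is auditable gene-by-gene and portable across datasets. Graph
clustering, embeddings, imputation, velocity and pseudotime are outside
this package's scope; a user who needs them can run them on the same
`SingleCellExperiment` container.

## Preprocessing

Stages run in a fixed order: gene prevalence filter → cell QC →
log-normalization.

* `filterGenesMinCells()` removes genes expressed in fewer than 3 cells
  (configurable). Whether this filter runs before or after cell QC is not
  dictated by the procedure being reproduced; we fix gene-filter-first for
  reproducibility. The two orders differ only for genes whose prevalence
  straddles the cutoff among QC-failing cells.
* `qcFilterCells()` removes cells with < 2500 or > 7500 detected genes
  (count > 0 — *detected*, not total UMIs) or > 10% mitochondrial counts.
  All comparisons are strict as printed, so boundary cells are kept.
  Mitochondrial genes are matched by the mouse `mt-` prefix,
  case-insensitively.
* `normalizeLog()` computes `ln(1 + c·s/total)` with scale factor
  `s = 10,000` and natural log — the defaults of the standard single-cell
  workflow the thresholds were calibrated on. Zeros map to zeros and each
  cell's vector is invariant to rescaling its counts. Every downstream
  threshold lives on this scale.

## The classifier

`classifyCellTypes()` evaluates conjunctions of strict clauses
(`gene > t` or `gene < t`) per cell. The shipped `defaultRuleSet()` holds
the six published rules (qNSC, aNSC, TAP, NB, OL, Astro). Design points
that were genuinely open:

* **Tie-breaking.** The printed aNSC and TAP rules are mutually exclusive
  through Dlx1/Dlx2, but collisions are still possible elsewhere
  (e.g. OL/Astro clauses do not mention each other's genes). We resolve
  multi-rule matches by the priority NB > TAP > aNSC > qNSC > OL > Astro —
  the most differentiated compatible identity wins — and flag every such
  cell in `type_ambiguous` so no collision is silent.
* **Missing genes are errors.** A rule gene absent from the matrix stops
  the run with the list of missing symbols; treating it as zero would
  silently satisfy exclusion clauses.
* **Unruled populations.** No thresholds are published for ependymal,
  endothelial/mural or microglial cells; they surface as `unassigned`.
  An optional EC rule (`Foxj1 > 0.5`) is available behind
  `defaultRuleSet(include_ec = TRUE)` but stays off by default because its
  threshold is this package's choice, not a published one.
* **Imputation.** We evaluate thresholds on raw normalized values, not on
  denoised/imputed data; the source workflow used imputation for display
  only, and thresholds on imputed values would not be comparable.

`assignLineage()` implements the pallial/subpallial panels at threshold
0.25 with the published any/all structure; cells above threshold on both
sides are *dual*. A value exactly equal to a threshold satisfies neither
a `>` nor a `<` clause, which is why the four lineage categories still
partition all cells. `stratifyHopx()` cuts quiescent cells at
`Hopx > 2.5` / `< 0.4` on the same normalized matrix as classification.

`rnaContentCheck()` addresses the obvious doublet explanation for dual
cells: a pallial+subpallial doublet carries roughly the summed RNA of two
cells, a genuine dual cell does not. The check reports mean total UMI of
dual versus single-lineage cells with a rank-sum p-value and leaves the
interpretation to the caller.

## Cell-cycle scoring

`scoreCellCycle()` follows the standard bin-control strategy: genes are
cut into `n_bins = 25` equal-frequency bins by dataset-mean expression;
for each marker gene, up to `n_ctrl = 100` control genes are sampled
(seeded, without replacement, marker genes excluded) from its bin; the
score is mean(marker) − mean(controls). A cell is S or G2M only when the
corresponding score is maximal *and positive* — cells expressing neither
program are likely not cycling and fall into G1/G0. Ties between two
positive scores resolve to G2M; exact ties are a measure-zero event on
real data and only arise in degenerate fixtures. The marker lists are
inputs (GMT); we ship the standard mouse S/G2M lists as a packaged
default because the procedure being reproduced names the strategy but not
the genes.

## Signature AUC

`aucScore()` integrates the step recovery curve of a gene set over the
top `k = ⌈0.05·n⌉` positions of a cell's expression ranking and
normalizes by the best achievable area:

\[ \mathrm{AUC} = \frac{\sum_{i=1}^{k} \mathrm{hits}(i)}
                      {\sum_{i=1}^{k} \min(i, m)},\qquad
   m = \min(|S \cap \mathrm{genes}|, k) \]

so a set packed at the top scores exactly 1 and a set entirely outside
the top `k` scores exactly 0, and scores are comparable across set sizes.
Decisions that the method description leaves open:

* `top_fraction = 0.05` is the reference implementation's default and is
  configurable.
* Ties are broken by one seeded random permutation applied consistently
  across cells, so the score depends on ranks only (invariant to any
  monotone transform of a cell's values).
* Signature genes absent from the matrix are dropped with a logged count;
  an empty intersection yields `NA`, never a fake 0.
* `k` is computed as `ceiling(top_fraction · n − 1e-9)`; the epsilon
  guards against floating-point noise on exact multiples.

## Differential expression

`wilcoxonDE()` mirrors the standard marker test: genes detected in at
least 10% of either group and with |avg_logFC| ≥ 0.25 are tested;
`avg_logFC = ln(mean(e^{x_1}−1)+1) − ln(mean(e^{x_2}−1)+1)` on
normalized values (the v3 convention of the referenced tool; the printed
"0.25 average fold change (log scale)" does not fix the formula, so this
is a declared choice). P-values are exact (via the tie-free null
distribution) when the pooled sample is ≤ 12 without ties, and use the
normal approximation with tie correction otherwise. Bonferroni
multiplies by the *total* number of genes in the matrix — the pre-filter
universe, reading "total number of genes in the datasets" literally. The
enrichment filter (p < 0.05, logFC ≥ 0.25, ≥ 25% detection in the
cluster of interest) defaults to raw p because the printed filter does
not say "adjusted"; an adjusted-p mode exists.

## The synthetic generator

`simulateCounts()` emulates the statistical structure the thresholds
assume, with planted truth for every label the pipeline produces. The
model: gene-wise negative binomials with log-normal cell size factors
(`meanlog = log(30000)`, `sdlog = 0.25` — high-coverage 10x libraries),
a shared dispersion per gene class (background size 10, marker size 20),
a mitochondrial block (13 `mt-` genes, 5% of counts), and on/off marker
programs per cell.

Key design decisions, with the reasoning:

* **Program placement.** `buildMarkerPrograms()` defaults to the pure
  ±margin formula (on/off at `t(1±margin)`). The generator itself uses
  margin 2 with an on-state floor of 3.0 and cap of 4.0 (normalized-log
  units), and silences off-programs entirely. The floor exists because
  counting noise is absolute, not relative: an on-state at 1.2 for a
  threshold of 0.6 corresponds to only ~2 expected UMIs per 10⁴ and drops
  below threshold in a non-negligible fraction of cells, while the printed
  exclusion thresholds (0.01–0.5) all sit below `ln 2`, so a *single* UMI
  violates them after normalization — the off state must be silence. The
  cap keeps extreme thresholds (Aqp4 > 2, Hopx > 2.5) from consuming a
  distorting share of the library.
* **Composition.** Default proportions are the published mix
  (52/17/17/6.6/5.4/1/0.5%); an "other" class at 0.5% (endothelial/mural,
  microglia) closes the simplex.
* **Lineage structure.** TAP and NB cells are always planted subpallial
  (or dual): the TAP rule itself requires `Dlx2 > 0.01`, and any
  realizable on-state for Dlx2 also crosses the 0.25 lineage threshold, so
  a pallial TAP is unrealizable under the rules themselves — consistent
  with TAPs/NBs being predominantly subpallial in this niche. Sp8 and Gad2
  occur only in exclusion clauses; they are planted in NB cells
  (GABAergic neuroblasts) so they survive the 3-cell prevalence filter.
* **Deep quiescence.** A configurable fraction of qNSCs (default 0.53)
  is Hopx-high; those cells also receive the deep-quiescence signature
  and a scaled-down baseline (`deep_detected_factor`) emulating reduced
  transcriptional output. At the default 3000-gene scale the QC floor of
  2500 detected genes sits at 83% of the genome, so a double-digit
  detected-genes contrast would push deep cells below QC and corrupt the
  planted-violator semantics; the default factor (0.7) therefore keeps
  detection saturated, and the ~12% reduced-detection phenotype is
  demonstrated with a wider genome (6000 genes, factor 0.5), where it
  fits comfortably above the QC floor.
* **Violators and doublets.** QC violators are whole-cell scalings
  (low-gene cells ×0.02 everywhere; high-mito cells boost only the
  mitochondrial block to ~25%), so each violator fails for exactly one
  reason. Doublets are plain sums of two sampled cells' counts, no depth
  rescaling — the RNA-content check is meant to expose exactly that
  signal. `highgene_rate > 0` is rejected unless the genome exceeds 7500
  genes (otherwise the violation is unrealizable).
* **One seed, one stream.** The whole simulation runs under a single
  seeded RNG stream restored afterwards; no hidden global state.

What the generator does *not* emulate: gene–gene correlation beyond the
planted programs, batch effects, ambient RNA, gradual (non-bimodal)
marker expression, or spliced/unspliced layers. Passing tests on this
generator therefore demonstrates the pipeline's correctness and
calibration under the assumed model, not robustness to every failure
mode of real data — in particular, real marker distributions are
continuous, so real recovery rates will depend on how well separated the
populations actually are.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline at 5000
cells × 3000 genes (one shared simulation), unit tests at 120–1500 cells,
the AUC oracle on 1000 random 100-gene instances, DE null/power at 2000
genes with 100–200 cells per group, and determinism at 800 cells. Small
unit-test simulations boost the rare-type proportions so every rule gene
clears the 3-cell prevalence filter; acceptance-scale runs use the
default composition. Exactness policies: rank-sum p exact iff pooled
n ≤ 12 and tie-free (enumeration-verified); signature comparisons exact
up to 50 per group; everything else normal approximation with tie
correction. All equality comparisons on thresholds are strict;
degenerate inputs (zero-total cells, empty subsets, missing genes, empty
gene-set intersections) raise errors or flagged `NA`s rather than
silent coercions.

## Known limitations

* Cells of types without published rules are `unassigned`; the package
  deliberately does not invent thresholds for them (the optional EC rule
  excepted, and it is off by default).
* The Bonferroni universe is the post-gene-filter matrix; if a caller
  filters genes differently the universe follows the matrix they pass.
* The classifier is sensitive to normalization scale by construction —
  thresholds are meaningful only on the `ln(1 + c·10⁴/total)` scale.
* `readMTXTriplet()` covers the plain and gzipped triplet dialects
  (`features.tsv`/`genes.tsv`); HDF5 and loom containers are out of
  scope.
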