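# advcomm

Ligand–receptor cross-talk analysis for annotated single-cell RNA-seq data,
built for studies that ask *which cell types talk to which* — for example,
how adventitial mesenchyme subsets (Mesen I–IV, Sca-1⁺ "Mesen II") attract
macrophages and other immune cells in the aortic adventitia of wild-type
versus hyperlipidemic (ApoE⁻/⁻) mice. It is aimed at analysts who already
have a clustered count matrix and want a transparent, testable communication
score rather than a black box.

## The score

Let `f_C(g)` be the **expressing fraction** of gene `g` in cell type `C`:
the proportion of `C` cells with a nonzero measurement of `g`. Given an
ordered pair of cell types `(A, B)` (A supplies the ligand, B the receptor)
and a curated list of ligand–receptor pairs `p = (l_p, r_p)`, a pair is
counted for a cell couple when both genes are detected, and the **mean
interaction number** is

```
M(A, B) = ( # of triples (p, i ∈ A, j ∈ B) with x[l_p, i] > 0 and x[r_p, j] > 0 ) / (|A| · |B|)
        = Σ_p f_A(l_p) · f_B(r_p)
```

The per-pair score `s_p(A, B) = f_A(l_p) · f_B(r_p)` lies in `[0, 1]`;
`M` is bounded by the pair-universe size. Because only positivity enters,
the scores are identical on raw counts and on any zero-preserving monotone
transform such as log-normalized data — the package tests this invariance.

Around this core the package provides:

* **QC filtering** — cells expressing fewer than 200 or more than 2,500
  genes, or with mitochondrial count fraction above 0.05, are removed
  (inclusive boundaries; all thresholds configurable).
* **Log-normalization** — `ln(1 + 10^4 · count / cell total)`.
* **Cell-cycle scoring** — mean set expression minus the mean of `10n`
  control genes matched on mean expression and detection frequency.
* **Genotype comparison** — regularized `log2((M_ko + ε) / (M_wt + ε))`.
* **Downsampling robustness** — every cell type repeatedly downsampled to
  the smallest type's size to show the interaction pattern is not a
  cell-number artifact.
* **Over-representation** — hypergeometric tail test of a query list (e.g.
  ligands of the top-200 interactions) against GMT gene sets, BH-adjusted.
* **A seeded simulator** — negative-binomial counts with *planted*
  expressing fractions and QC-offender cells, so every claim above is
  verified against known ground truth.

## Worked example

Simulate two genotypes with a planted Gene0001→Gene0002 axis from Mesen II
to inflammatory macrophages (wt fractions 0.4/0.3, knockout 0.8/0.6), run
QC, and score the cross-talk:

```r
library(advcomm)

spec <- synthetic_spec(
  cells_per_cluster = 200, seed = 42,
  planted_fractions = data.frame(
    genotype = rep(c("wt", "apoe_ko"), each = 2),
    cluster  = rep(c("Mesen_II", "Mac_inflammatory"), 2),
    gene     = rep(c("Gene0001", "Gene0002"), 2),
    fraction = c(0.4, 0.3, 0.8, 0.6)))
sim <- simulate_adventitia(spec)

qc <- filter_cells(sim$counts, qc_thresholds())
table(qc$report$removed_by)
#>           high_gene high_mito  low_gene
#>      2256        48        48        48

ann   <- sim$annotation[match(colnames(qc$counts), sim$annotation$barcode), ]
pairs <- data.frame(ligand = "Gene0001", receptor = "Gene0002")

ko    <- ann[ann$genotype == "apoe_ko", ]
fr_ko <- expressing_fractions(qc$counts[, ko$barcode], ko,
                              genes = unique(unlist(pairs)))
M_ko  <- mean_interaction_matrix(fr_ko, pairs)
round(M_ko["Mesen_II", ], 3)
#>          Mesen_I         Mesen_II        Mesen_III         Mesen_IV
#>            0.343            0.176            0.411            0.485
#>     Mac_resident Mac_inflammatory
#>            0.373            0.541
```

Two percent of the 2,400 simulated cells were planted as QC offenders of
each class; the filter removes exactly those 144 cells and no others. The row of
`M_ko` reads: with Mesen II as the ligand cell type, the mean number of
active Gene0001→Gene0002 interactions per (ligand cell, receptor cell)
couple, for every receptor cell type. The 0.541 toward inflammatory
macrophages reflects the planted 0.8 × 0.6 axis plus that cluster's
background receptor expression.

```r
wt    <- ann[ann$genotype == "wt", ]
fr_wt <- expressing_fractions(qc$counts[, wt$barcode], wt,
                              genes = unique(unlist(pairs)))
cmp <- compare_genotypes(mean_interaction_matrix(fr_wt, pairs), M_ko)
round(cmp$log2_ratio["Mesen_II", "Mac_inflammatory"], 2)
#> [1] 2.25
```

The knockout shows ~4.8-fold stronger Mesen II → inflammatory-macrophage
signaling, close to the planted `log2((0.8·0.6)/(0.4·0.3)) = 2`.

A small curated-style pair list ships at
`system.file("extdata", "lr_pairs_example.tsv", package = "advcomm")` for
use with `read_lr_pairs()`.

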