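---
title: "Expression-positivity cross-talk scoring: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-positivity cross-talk scoring: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(advcomm)
```

## The model

`advcomm` quantifies directed cell–cell communication from a clustered
single-cell count matrix using only *expression positivity*. For cell type
$C$ and gene $g$, the expressing fraction is

$$f_C(g) = \frac{|\{i \in C : x_{g,i} > 0\}|}{|C|},$$

and for an ordered pair of cell types $(A, B)$ and a ligand–receptor pair
universe $P$, the mean interaction number is

$$M(A, B) = \frac{1}{|A||B|} \sum_{p \in P} \sum_{i \in A} \sum_{j \in B}
  \mathbf{1}[x_{l_p,i} > 0]\,\mathbf{1}[x_{r_p,j} > 0]
  = \sum_{p \in P} f_A(l_p)\, f_B(r_p).$$

Rows of $M$ always index the ligand cell type. The implementation sums the
integer positive-cell-count products and divides once by $|A||B|$, so it is
bit-identical to the literal triple-loop counting rule; the factorized form
is what the tests verify against an independent brute-force oracle.

Assumptions worth stating plainly:

* **Transcript positivity stands in for protein-level signaling.** The score
  predicts *potential* interactions; it knows nothing about secretion,
  distance, or receptor occupancy.
* **Detection is binarized.** A gene detected in one read counts as much as
  one detected in a hundred. This makes the score invariant under any
  zero-preserving monotone transform — raw counts and log-normalized values
  give identical results, which the package asserts rather than assumes.
  For that reason positivity is always evaluated with a strict `> 0`
  threshold, never a float comparison against a normalized value.
* **No significance model.** The score is descriptive; cluster-label
  permutation nulls are deliberately out of scope.

## Pipeline parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_genes`, `max_genes` | 200, 2500 | Inclusive window of detected genes per cell; cells expressing fewer than 200 (ambient/empty) or more than 2,500 (likely aggregates) are removed. |
| `max_mito_fraction` | 0.05 | Cells with mitochondrial count fraction strictly above this are removed (stressed/dying cells); exactly 0.05 is retained. |
| `mito_prefix` | `"mt-"` | Mouse mitochondrial symbol prefix; configurable for other organisms. |
| `scale_factor` | 10⁴ | Counts-per-ten-thousand before `log1p`; natural log. |
| `controls_per_gene` | 10 | Matched control genes per set gene in cycle scoring. |
| `epsilon` | $1/(N_{wt} N_{ko})$ | Regularizer for genotype log-ratios — the smallest resolvable score given the two total cell numbers, so a 0-vs-0 entry maps to 0. |

Boundary semantics are a deliberate literal reading of the printed filter
inequalities ("fewer than 200 or more than 2,500", "above 0.05"): the
boundary values themselves are retained. The gene-count and mitochondrial
rules are applied jointly in one pass; they are conjunctive, so order cannot
change the result.

## Cell-cycle scoring

The G1/S or G2/M score of a cell is the mean normalized expression of the
$n$ phase genes minus the mean of $10n$ control genes. The published
description of the control set — the "$10n$ nearest neighbors by expression
level and detection frequency" — names two coordinates but no metric, so the
package fixes the simplest faithful reading: per-gene mean log-expression
and detection frequency are standardized to z-scores across genes, and each
set gene contributes its `controls_per_gene` nearest non-set, not-yet-chosen
genes by Euclidean distance, ties broken by gene order. Controls are chosen
once per set, not per cell, and pooled controls number exactly $10n$. An
alternative reading — the $10n$ globally nearest genes to the set centroid —
was considered and rejected because per-gene matching is what makes the
control set track a heterogeneous phase set's expression profile.

Under exchangeability (set genes drawn from the same distribution as the
background) the score is centered on zero; a planted $+2$ shift in set-gene
expression is recovered within binomial-normal error. Both properties are
exercised in the test suite at $n = 300$ cells.

## The synthetic generator

`simulate_adventitia()` is first-class, tested code, not a fixture. It
emulates the structure of a two-condition adventitia experiment at desk
scale: two genotypes (`wt`, `apoe_ko`) × six clusters (Mesen I–IV plus two
macrophage types) × 300 cells, 3,000 nuclear genes and the 13 mouse
mitochondrial genes. Counts are negative binomial with variance
$\mu + \phi\mu^2$ (default $\phi = 0.5$), per-gene lognormal factors, and
per-(gene, cluster) lognormal multipliers for cluster structure.
Mitochondrial genes get a fixed elevated mean and no cluster structure so
the background mitochondrial fraction sits near 1%, far from the 0.05
cutoff.

Three design points matter:

* **Planting is Bernoulli gating of a zero-truncated draw.** For a planted
  record $(genotype, cluster, gene, f)$, each non-offender cell is gated on
  with probability $f$; gated-on cells draw from the zero-truncated NB,
  gated-off cells are zero. The positivity fraction is therefore controlled
  exactly in expectation regardless of NB parameters, decoupling the
  quantity the cross-talk module estimates from count magnitudes. The truth
  object records both the target and the realized (materialized) fraction.
* **Offenders violate exactly one rule by construction.** Low-gene cells
  express exactly 50 genes; high-gene cells express
  $\min(\text{genes}, 3000)$ genes at count 1 (mitochondrial share ≈ 0.4%,
  safely legal); high-mito cells get a mitochondrial share drawn uniformly
  in (0.10, 0.30) at ~400 expressed genes. Offenders are assigned before
  planting so planted fractions refer to the QC-surviving population.
  Because the high-gene class needs more than 2,500 expressible genes, the
  default gene count is 3,000 (the generator errors rather than silently
  producing a non-offending "offender").
* **Determinism.** All randomness flows from one seed, split into four
  stage sub-seeds (means, base counts, offenders, planting), so identical
  specs produce byte-identical output and stages stay comparable when one
  changes.

What the simulator does **not** emulate: realistic library-size variation
beyond NB dispersion, batch or chemistry effects, doublet expression
profiles (the high-gene offender is a caricature), gene–gene correlation,
and the long-tailed cluster-size imbalance of real tissue. Passing tests
therefore show that the *computations* are correct and calibrated on data
matching their assumptions — not that the biological conclusions of any
particular real dataset would be robust to, say, ambient RNA contamination.

## Numerical choices

* Interaction numerators are integer sums divided once, exact for any count
  of cells representable in a double (well beyond 10⁷ cells).
* Ranking ties break deterministically: score descending, then ligand,
  receptor, ligand type, receptor type in byte order (`method = "radix"`),
  so output is locale-independent.
* Downsampling dispersion reports exactly 0 when every repeat produces the
  same matrix (equal type sizes), avoiding spurious 10⁻¹⁷-scale noise from
  accumulated floating-point means.
* Written TSV matrices carry 17 significant digits so read-back is
  value-identical.
* The genotype log-ratio of two zero entries is 0 by the $\varepsilon$
  regularization, not NaN.

## Validation problem sizes

The test suite fuzzes the oracle comparison on 100 instances of up to 50
cells, 20 genes and 10 pairs; parameter recovery uses 500 cells per cluster
with planted fractions (0.6, 0.5) checked within three delta-method standard
errors of 0.30; downsampling uses 100 repeats on unequal cluster sizes
(280 down to 80 cells). These sizes were chosen so the full validation runs
comfortably on a laptop while keeping binomial standard errors small enough
for three-sigma checks to be informative.

## Known limitations

* The curated pair list is an input; the package ships only a 20-pair
  illustrative example, and results are only as good as the supplied list.
* Gene-set restriction of the pair universe defaults to requiring *both*
  members in the set; an `"either"` mode exists because figure-legend-style
  descriptions of "ligands and receptors from a gene set" are ambiguous.
* Cluster labels are taken as given; mis-clustered cells bias expressing
  fractions in ways no downstream arithmetic can repair.
* The hypergeometric over-representation test treats genes as exchangeable
  units; it replaces external annotation-database tooling with a generic,
  reproducible operation on user-supplied sets, and makes no attempt to
  reproduce any specific database's vocabulary.
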