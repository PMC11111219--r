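---
title: "Methods: communication scoring, module scores and the synthetic study"
author: "commscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: communication scoring, module scores and the synthetic study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commscore)
```

# Scope and model

`commscore` quantifies cluster-to-cluster crosstalk in droplet scRNA-seq.
The pipeline is deliberately simple and fully specified: every number it
produces can be recomputed by hand from the count matrix, which is the point
of re-implementing this analysis as a package rather than a notebook.

The stages are:

1. **Per-cell QC** on four metrics: detected genes (`n_features`), total
   UMIs (`n_counts`), mitochondrial UMI percentage and ribosomal UMI
   percentage.
2. **Log-normalization**: `v = ln(1 + c · sf / N)` with scale factor
   `sf = 10^4` (counts per 10K).
3. **Cluster profiles**: arithmetic means `μ_{g,c}` of normalized values
   over all cells of a cluster, zeros included.
4. **Communication scores**: for each directional ligand→receptor pair and
   ordered cluster pair (A, B), `s = f_L(A) × f_R(B)`, where `f` is `μ` for a
   single gene and a combination of subunit means for complexes. Per ordered
   cluster pair, scores with `s > τ` (default `τ = 6`, strict) are summed
   (`S`) and counted (`n`).
5. **Module scores**: mean normalized expression of a gene set minus that of
   expression-matched control genes.
6. **Composition**: cluster percentages per condition and their differences
   in percentage points.

# Boundary semantics and parameters

QC keeps a cell iff all four hold:

| metric | rule | default |
|---|---|---|
| `n_features` | inclusive window | \[200, 6000\] |
| `n_counts` | strictly greater | > 1000 |
| `pct_mito` | strictly below | < 15 |
| `pct_ribo` | strictly below | < 40 |

The feature window is read as inclusive ("between 200 and 6000"); the
molecule cut follows the code-like form `nCount_RNA > 1000` (strict) rather
than the looser "at least 1000", and the percentage cuts are strict
("below"). All four are parameters of `qc_thresholds()`, so the alternative
readings are one configuration change away; the criteria commute, so the
surviving set is order-independent. Mitochondrial genes are matched by the
prefixes `mt-`/`MT-` (mouse and human conventions) and ribosomal genes by
`Rps`/`Rpl`; the prefixes are recorded in the QC report because a silent
prefix mismatch is the most common QC bug.

Cells failing QC are removed before normalization; a zero-total cell makes
`log_normalize()` fail loudly rather than emit NaNs (its mito/ribo
percentages are defined as 0 in the QC table, with a warning, since it is
removed by the molecule cut anyway).

**Normalization choice.** Upstream toolchains vary in what "normalized
expression" means (regularized models, scaled data, etc.). This package
pins the standard log1p-of-CP10K transform and records scheme and scale
factor in the output metadata, because the communication score is defined on
mean normalized expression and must be exactly reproducible. Consequently,
absolute score values are comparable only between runs using the same
normalization.

# Communication scoring decisions

* **Threshold placement.** The threshold is applied to *individual*
  pair scores before summation: interaction *counts* "with communication
  score > 6" are only meaningful per pair, and the aggregate is then the sum
  of surviving pair scores. Both the per-pair table and the aggregated
  network are persisted, so the alternative reading (thresholding the
  aggregate) is recomputable from the same outputs.
* **Strictness.** `s > τ` with `τ = 6`; a score of exactly 6 is excluded.
* **Complexes.** A multi-subunit ligand or receptor contributes the
  *minimum* of its subunit cluster means — the complex is limited by its
  least-expressed subunit. `mean` and `geomean` are available as
  `complex_rule` since no canonical choice exists.
* **Self-loops** (A = B) are computed but reported separately by
  `outgoing_interaction_counts()`, since crosstalk summaries count
  interactions toward *other* clusters.
* **No normalization of `S`** by pair count or cluster size: the aggregate
  is a raw sum, so `S > n·τ` whenever `n > 0`.
* **Conditions are scored separately** by default (`lr.per_condition`):
  pooling conditions before cluster means would mix genotype-specific
  expression into one profile. The choice is recorded in the run manifest.

Useful invariants, all under test: bilinearity (scaling a cluster's ligand
means by `k` scales its outgoing scores by `k`), zero annihilation (either
factor 0 gives `s = 0`), directionality (ligand is always read from the
source cluster), and equality with a brute-force double loop at `1e-12`.

# Module scores

For gene set `G`, the per-cell score is
`M = mean_{g∈G}(v_g) − mean_{g∈ctrl}(v_g)`. Control genes are matched for
expression level: all genes are ranked by mean normalized expression and cut
into `n_bins = 24` equal-size rank bins (ties broken by matrix order, so the
binning is exactly deterministic); for each set gene, `n_ctrl = 100` controls
are drawn without replacement from its bin, and the pooled controls
(duplicates collapsed) are averaged. Scores are location-equivariant (adding
δ to the set genes shifts `M` by exactly δ) and deterministic given the seed.

Two deliberate policies differ from some common implementations and slightly
change absolute scores:

* the control pool **excludes the set genes**, so the null is not
  contaminated by the signal being tested;
* controls are sampled **once per (matrix, set, seed)**, not per cell,
  keeping scores comparable across cells.

If excluding set genes empties a bin, the nearest non-empty bin is used with
a warning (ties toward lower bins). Set genes absent from the matrix are
dropped and reported, never silently imputed. Gene-symbol matching is
case-sensitive by default (mouse vs human capitalization carries
information); `resolve_pairs()` offers an explicit case-insensitive mode.

# Composition

Percentages use pooled cells per condition (typical small per-arm sample
counts make per-sample means noisy; a `group_key` switch allows per-sample
analysis). The union of clusters across conditions is used everywhere, so a
cluster absent from one condition contributes `p = 0` rather than a missing
row; percentages then sum to 100 per condition and signed differences sum to
0 exactly — both asserted in the tests. Signed and absolute differences are
both emitted: figures typically show `|Δ|`, but the sign is analytically
useful and free.

# The synthetic study

`default_sim_config()` emulates the shape of a two-genotype immune-cell
experiment: a control genotype with a full resident-macrophage compartment,
and a depleted genotype (`dfire`) in which homeostatic and antigen-presenting
macrophages drop sharply while neutrophils and classical monocytes expand.
Its defaults are fixed study conditions, not tuning knobs:

* 2 conditions × 1000 cells, 10 clusters (four macrophage states,
  neutrophils, classical monocytes, B/T/NK cells, dendritic cells);
* 2000 genes; per-gene baseline rates lognormal (sdlog 1) with mean 1.5
  UMI/gene, giving per-cell depths around 3000 UMIs and ~1000 detected
  genes — comfortably inside the QC window;
* negative-binomial counts with shared dispersion (size) 2, i.e.
  `var = μ + μ²/2` — the minimal over-dispersion needed for realistic QC
  metrics and cluster means (verified empirically in the tests at 10,000
  cells);
* 10 marker genes per cluster at 8-fold enrichment;
* 13 `mt-` genes at a 5% expression share and 40 `Rps`/`Rpl` genes at 20%.
  Rates are uniform *within* each class: this keeps per-cell mito/ribo
  percentages tightly concentrated (roughly 5 ± 1% and 20 ± 2%), so
  background cells sit far from the 15%/40% QC boundaries and the planted
  QC failures are the only cells that cross them;
* 3 planted ligand–receptor interactions (one with a two-subunit receptor)
  whose genes are near-silent (rate 0.1) except in their source/target
  cluster (×100), giving expected per-pair scores ≈ 9 — above τ = 6 with a
  margin recorded in the ground truth; 50 decoy pairs expressed uniformly at
  rate 0.5 score ≈ 0.5, far below threshold;
* a 20-gene module whose rates are scaled in the `dfire` condition so the
  induced mean log-normalized shift is 0.5. The multiplier is found by
  solving `mean_g E[ln(1 + c·sf/N)] − (unshifted)` = δ numerically
  (`uniroot`), with the expectation taken over the negative-binomial pmf at
  the expected cell total; the calibrated multiplier is stored in the truth;
* 4 junk cells per QC failure mode, with barcode prefix `JUNK-` so truth
  matching is unambiguous: few-features cells (60 genes at healthy depth),
  shallow cells (~400 total UMIs), and cells with mito (~50%) or ribo
  (~60%) shares far beyond the cuts.

What the generator does **not** emulate: batch effects, ambient RNA,
doublets, gene–gene correlation beyond cluster structure, or the scale of a
real atlas. Passing tests therefore demonstrate the *correctness of the
computations* — threshold semantics, recovery of planted effects under NB
noise, determinism — not robustness to the artifacts of real tissue data.

# Problem sizes and runtime choices

The validation suite runs everything at desk scale, chosen to keep the
statistical targets meaningful: oracle equivalence on 5 clusters × 200 genes
× 500 cells × 50 pairs; QC exactness and end-to-end determinism on the full
default study (~2000 × 2016); module-shift recovery over 20 seeds and
planted-interaction recovery over 50 seeds on reduced gene panels (600–800
genes) whose baseline rates are raised (4–5 UMI/gene) so per-cell depth
stays ~3000 — recovery targets depend on cells and effect sizes, not on the
number of background genes. Abundance recovery uses ±3 pp at 1000
cells/condition, i.e. about two binomial standard deviations for a 25%
cluster.

# Known limitations

* No statistical test accompanies the communication scores (no permutation
  null); the threshold is a fixed operating point, as in the figure-style
  summaries this reproduces.
* Scores depend on cluster granularity and on the normalization scheme;
  comparisons are only valid within a run configuration.
* The LR database is an input; the package ships no curated pair list and
  no ortholog mapping.
* `cluster_means()` treats cluster labels as given; clustering itself is out
  of scope.
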