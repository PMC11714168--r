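---
title: "Scoring cell infiltration through per-sample crosstalk networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring cell infiltration through per-sample crosstalk networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(InfilNet)
```

## Model

InfilNet scores the relative infiltration of cell types in a bulk
transcriptome by network centrality rather than by per-signature enrichment.
The underlying assumption is that a cell type's activity in a tissue is
shaped by its functional neighborhood: cell types engaged in many shared
biological processes with other transcriptionally active cell types are
taken to be more present. Three ingredients enter:

* a collection of cell-type signature gene sets (cells), each annotated as
  lymphoid, myeloid, stem, stromal or other;
* a collection of GO biological-process gene sets (functions), size-filtered
  to 15–350 genes — below 15 genes overlap statistics are dominated by single
  genes, above 350 the terms are too generic to indicate a specific function;
* one sample's expression vector on a non-negative log-like scale
  (log2(TPM+1) or log2(FPKM+1)).

For a sample, the bipartite weight between cell set $C$ and GO set $G$ is

$$W_{C,G} = J_{C,G} \cdot \mathrm{med}\{e_x : x \in C \cap G\},$$

with $J_{C,G} = |C \cap G| / |C \cup G|$. The Jaccard factor measures how
strongly the cell type is implicated in the function; the median expression
of the shared genes measures how active that implication is in this
particular sample. The one-mode projection

$$R_{ij} = \sum_k W_{i,k} W_{j,k}, \qquad R_{ii} = 0$$

yields the cell–cell crosstalk adjacency: two cell types are linked exactly
when they share at least one GO term, with weight accumulating over all
shared terms. Cell infiltration is then the stationary distribution of a
random walk with uniform restarts on this weighted network,

$$\pi \leftarrow r\,u + (1 - r) P \pi,$$

where $P$ is the column-normalized adjacency, $u$ the uniform vector and
$r$ the restart probability. The stationary $\pi$ is an eigenvector-type
centrality: cells sitting in heavy neighborhoods accumulate walker mass.
Finally, per sample, scores are $\log_{10}$-transformed (raw stationary
scores are heavy-tailed, close to a power law) and min–max normalized to
$[0, 1]$, giving the InScore column for that sample.

## Parameters that matter

* **`restart_prob`** (default 0.15, dimensionless, in (0, 1]). Not fixed by
  the method's description; 0.15 is the conventional damping complement in
  restarted-walk centrality. Because InScores are relative and min–max
  normalized, what matters is rank stability: the test suite checks that
  rankings are essentially unchanged for $r \in [0.05, 0.5]$. `r = 1`
  degenerates to the exact uniform distribution.
* **Set-size band** (defaults 15 and 350 genes) for GO terms, inclusive at
  both ends.
* **Prevalence filter** (default: expressed in ≥ 50% of samples, where
  "expressed" means strictly greater than 0 on the log scale; both the
  fraction and the threshold are exposed). With a single sample the filter
  degenerates to "gene > threshold", which is allowed — the per-sample
  network needs no cohort.
* **`dangling_policy`**: a cell sharing genes with no expressed GO term has
  zero degree. The default (`uniform_redistribute`) lets the walker jump
  uniformly from such nodes, keeping every score strictly positive so the
  downstream $\log_{10}$ is always defined.
* **Convergence**: L1 tolerance `1e-10`, at most 1000 iterations. The
  iteration is a contraction with factor $1 - r$, so convergence is
  geometric; non-convergence is reported with a warning and a flag, never
  silently.

## Design choices in ambiguous territory

* **Gene universe.** Jaccard coefficients and medians are computed after
  restricting both collections to the measured (post-filter) genes. Mixing
  universes would make $J$ and the median inconsistent — the median is only
  defined over measured genes. A `restrict = FALSE` escape hatch exists for
  sensitivity analysis.
* **Order of transforms.** $\log_{10}$ is applied before min–max
  normalization: the log is introduced precisely to tame the raw scores'
  tail before the column is rescaled.
* **Median convention.** Even-sized overlaps use the standard
  midpoint-average sample median.
* **Constant columns.** A column where all cells tie (e.g. a single-cell
  network, or an all-zero expression vector, where the crosstalk matrix is
  identically zero and the stationary distribution exactly uniform) has no
  min–max image; it is mapped to 0.5 everywhere with a prominent warning,
  preserving the [0, 1] bounds without NaN.
* **Duplicate expression rows** collapse to the highest-mean row,
  deterministically (first occurrence wins ties).
* **Minimum cell–GO overlap** to form an edge is one gene; weight zero
  arises only from empty overlap.
* **Factorization.** $W = J \circ M$ where only $M$ varies per sample; the
  implementation computes $J$ and the per-pair overlap index once per
  cohort and only recomputes medians per sample. This is algebraically
  identical to recomputing everything per sample (tested bit-identical).
* **Exclusion list.** The packaged list of cell types absent from solid
  tumors contains exactly the three documented types (pro-B cells,
  hematopoietic stem cells, common lymphoid progenitors) and is a plain
  text file users can extend; the full membership of that list is not
  enumerable from the method's description.

## What the synthetic generator emulates — and what it does not

`generate_synthetic()` draws a gene universe, signature sets, GO sets that
share genes with the signatures at a controlled `overlap_rate`, and a
log-normal expression cohort; designated cells' *exclusive* signature genes
(genes in exactly one cell set, so ground truth is unambiguous) can be
up-shifted by a known effect $\delta$ in designated samples.

Defaults are chosen once as a realistic small-scale testbed: 500 genes, 12
cells, 40 GO terms, 6 samples; signatures of 15–40 genes, i.e. inside the
method's own 15–350 operating band (signatures below 15 genes are exactly
what the size filter exists to exclude — they make overlap medians unstable
and the cell structurally peripheral); GO sets of 15–40 genes with
`overlap_rate = 0.5`; baseline expression `rlnorm(meanlog = 1, sdlog = 0.5)`,
giving values around 2.7 with a right tail, resembling log2(TPM+1) data.

```{r}
fx <- generate_synthetic(synthetic_spec(
  seed = 42, n_samples = 4,
  spike = data.frame(cell = "cell_03", sample = "s02", delta = 8)))
res <- compute_inscore_cohort(fx$expr, fx$cells, fx$gos)
round(res$scores[1:6, ], 3)
```

The spike-recovery experiment used in validation spikes one cell per
replicate at $\delta = 12$ — the shift that takes a baseline gene to the top
of the log2(TPM+1) dynamic range (~15) — and asks whether that cell attains
the top InScore in the spiked sample. Recovery is monotone in $\delta$ and
saturates: weak spikes ($\delta \le 4$) are often absorbed by topology
(large signatures have systematically higher Jaccard degree), top-of-range
spikes are recovered in ≥ 95% of replicates.

What the generator does **not** emulate: correlated co-infiltration of
related cell types, compositional (sum-to-one) structure of real mixtures,
gene–gene correlation within signatures, batch effects, or curated marker
biology. Passing tests on synthetic data therefore demonstrate the
*mechanics* of the pipeline (signal propagation, normalization, invariances),
not marker quality on real tissues.

The packaged 86-set signature collection is likewise a synthetic stand-in
that reproduces the documented composition (86 sets; 40 lymphoid, 15
myeloid, 11 stem, 11 stromal, 9 other; sizes within the band) with
synthetic gene symbols, so that collection-handling code paths are fully
exercisable; real analyses should use curated GMTs.

## Numerical notes

* The projection uses `tcrossprod` and then symmetrizes
  (`(R + t(R))/2`) so `R[i,j] == R[j,i]` holds exactly, not just to
  rounding; the diagonal is overwritten with 0 afterwards.
* Scaling a sample's expression by $\alpha > 0$ scales medians by $\alpha$
  and the crosstalk matrix by $\alpha^2$; with dyadic $\alpha$ the identity
  is float-exact, which the tests exploit.
* The stationary iteration starts at $u$; with `restart_prob = 1` it
  returns $u$ exactly, bypassing iteration.
* Worker counts or cohort composition never change a sample's raw scores:
  samples are processed independently after the cohort-level prevalence
  filter, and the returned vector is normalized to sum 1 within `1e-9`.

## Problem sizes used in the shipped validation

The test suite and the acceptance script run entirely on synthetic data at
small scale: the fixed 3-cell/2-GO worked fixture for equation-level
oracles; 1000 random networks of 2–8 nodes against a dense linear solve;
100 seeded spike-in replicates (12 cells, 40 GO terms, 2 samples each);
6-sample cohorts for normalization and homogeneity checks. These sizes make
every check an exact or near-exact comparison while keeping the whole
validation run in minutes on one CPU. Realistic inputs (86 cells, ~4000 GO
terms, hundreds of samples) use the same code paths; the cells × GO matrices
involved remain small enough to be handled densely.

## Known limitations

* InScores are relative within the designed comparison (within-sample,
  across cell types, and across samples after the per-sample min–max); they
  are not absolute cell fractions and do not sum to anything meaningful
  across cell types after normalization.
* Cell types whose signatures barely intersect the measured GO universe are
  scored mostly by the restart term, i.e. near-uniformly; the dangling
  policy keeps them defined but uninformative.
* The crosstalk notion is functional similarity through shared GO
  membership, not physical ligand–receptor signaling.
* Fitting risk-model coefficients (e.g. Cox regression) is out of scope;
  `ct_tme_score()` only evaluates a supplied linear model.
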