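---
title: "Methods: SOM integration of transcriptome and secretome data"
author: "secretomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SOM integration of transcriptome and secretome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secretomap)
```

# The problem

Filamentous fungi degrading plant biomass mount coordinated responses: sets
of co-regulated genes (frequently carbohydrate-active enzymes, CAZymes) are
transcriptionally induced on lignocellulosic substrates, and their protein
products are secreted into the culture medium. `secretomap` integrates the
two measurement layers — a bulk RNA-seq count matrix over a multi-substrate,
multi-replicate, multi-time-point design, and a spectral-count table of
proteins identified in culture supernatants — on a single two-dimensional
map: genes are clustered onto a self-organizing map (SOM) by their
expression profiles, secreted-protein detections are overlaid onto the same
nodes, and node-wise annotation enrichment attaches biological meaning to
the clusters. The fixed node layout makes every per-node quantity (mean
transcription, fold change, protein count, enrichment flag) directly
comparable across substrates and time points.

# Pipeline and models

## Filtering and normalization

Genes whose total raw count summed over all samples is **strictly greater
than 5** form the analysis universe; everything downstream operates on this
fixed universe. The threshold is interpreted as a total (not per-library)
count, the reading consistent with a single genome-wide universe.

Per-sample size factors use the median-of-ratios convention: with reference
genes $R$ (genes with no zero count in any sample),

$$ f_j = \operatorname{median}_{g \in R}
   \frac{c_{gj}}{(\prod_j c_{gj})^{1/m}}, $$

rescaled to geometric mean 1 for reportability (`rescale = TRUE`). Size
factors are relative scalings: multiplying one library by $\lambda$
multiplies its factor *relative to every other sample* by $\lambda$ (the
per-gene geometric means absorb $\lambda^{1/m}$), and leaves log2 fold
changes invariant.

Normalized values are $\log_2(c_{gj}/f_j + 1)$. The pseudocount keeps zeros
at zero; it biases values below roughly 5 counts, which matters little
because node-level statistics average over 25-gene clusters.

Per-time-point log2 fold changes are differences of replicate means against
the control substrate at the same time point. The optional per-gene
significance screen is a Welch unequal-variance test on replicate log2
values, adjusted per contrast by both Benjamini–Hochberg and Bonferroni
(`flag_significant_genes`, method tag `welch_log2`). This is a deliberate
replicate-level screen, not a count-model fit: node selection rests on
level and fold-change thresholds, not on these p-values, so a
negative-binomial GLM would add machinery without changing the headline
outputs.

## Map planning and batch SOM training

The grid is planned from a **resolution of 25 genes per node**: the target
node count is `round(n_genes / 25)`, columns are
`floor(sqrt(target / 1.26))` (clamped to at least 2) and rows
`round(target / cols)`. The aspect constant 1.26 produces a 24 × 19 map of
456 nodes for 11,430 genes. Node ids run 1..rows×cols in row-major order
and that layout is frozen across every output.

Training is batch SOM on the genes × samples matrix of normalized log2
values (all replicates, all conditions, both time points; no per-gene
standardization, so absolute level is part of the clustered pattern). Each
epoch assigns every gene to its best-matching unit (BMU; minimal Euclidean
distance, ties toward the lowest node id) and replaces each codebook with
the neighbourhood-weighted mean of its assigned vectors. Choices that
matter:

* **Initial radius** — the 2/3 quantile of all pairwise Euclidean distances
  between node grid coordinates, computed with the empirical-cdf
  interpolation (`quantile(..., type = 4)`); on a 2 × 2 grid this gives
  exactly 1.
* **Radius schedule** — linear decay from the initial radius to 1 across
  epochs.
* **Neighbourhood kernel** — a *cut Gaussian*:
  $h(d) = \exp(-d^2 / 2r^2)$ for grid distance $d < r$, zero beyond the
  radius (the BMU itself always updates). The cutoff makes the end of the
  schedule ($r = 1$) exactly k-means-style updates, so the map sharpens to
  local means instead of staying smoothed; a full-support Gaussian at
  $r = 1$ would permanently mix neighbouring codebooks.
* **Training length** — 1000 vector presentations per node
  (456,000 for the full-size map), converted to batch epochs as
  `ceiling(presentations / n_genes)` with a floor of 10 epochs.
* **Initialization** — seeded uniform draws within each feature's data
  range (PCA-plane initialization available via `init = "pca"`). Training
  is bit-reproducible given the seed.

The quantization error (mean gene-to-BMU distance) is recorded before and
after training and is asserted non-increasing in the test suite. Batch
updates with a shrinking truncated kernel are not guaranteed monotone
epoch-to-epoch, but start-to-end decrease holds in practice and is part of
the package's contract.

## Secretome overlay and node selection

A protein is *detected* in a sample when its spectral count reaches
`detection_min` (default 1 spectrum; peptide/protein-level validation is
assumed upstream). Background subtraction is global: any protein detected
in **any** control-condition sample, at either time point, is removed
everywhere. Retained proteins are mapped to nodes through their gene ids
(protein ids share the gene id namespace; unmatched ids are dropped with a
warning), giving per-node overall counts plus per-(condition, time) counts
based on detection within that cell.

*Secretion hotspots* are nodes whose protein count strictly exceeds the
90th percentile (R's default `type = 7` linear interpolation) of the
nonzero-count distribution; with a single protein-carrying node that node
is returned directly, since a strict comparison against the percentile of a
length-1 distribution would otherwise make the answer vacuously empty.

*Responsive nodes* per non-control (condition, time) cell satisfy either
criterion: mean log2 level strictly above the 90th percentile of all node
means (pooled over every cell; the realized cutoff is data-dependent, e.g.
11.7 on a full-scale fungal dataset), or node-level log2 fold change
strictly above 2. The node-level fold change defaults to the mean of member
genes' fold changes (`mode = "node_mean"`); `mode = "any_gene"` lifts the
criterion to "any member gene exceeds the threshold". Responsive sets per
condition are intersected into specificity labels (`shared_all`,
`shared_two:<pair>`, `specific:<condition>`).

## Node-wise term enrichment

For each node, namespace and term, the four hypergeometric parameters are
occurrence-based: $k$ term occurrences in the node, $n$ all occurrences in
the node, $K$ term occurrences genome-wide, $N$ all occurrences
genome-wide (one occurrence per annotated gene per term; the classic
`phyper(k - 1, K, N - K, n)` upper tail, inclusive of $k$). A gene-based
universe is available (`universe = "gene"`). Only terms appearing **at
least 3 times** in a node are admitted to testing ("more than twice");
totals are computed on the full counts. BH adjustment pools all admitted
tests across nodes and namespaces, and pairs with adjusted p below 0.01 are
flagged.

A consequence worth knowing (see Limitations): admission screening makes
the BH family conditional on observed clumping, so under a complete null
the procedure still emits occasional single false pairs. What the screened
procedure does keep below the nominal level is the rate of false calls over
the full node × term hypothesis space; the acceptance suite measures
exactly that.

## Response metrics

The transcription induction factor is TIF $= (\log_2 \text{FC})^2$.
Squaring discards sign, so the default output is restricted to up-regulated
entries ($\log_2$ FC > 0); repressed genes would otherwise masquerade as
induced. The node-level transcriptome–secretome association is Spearman's
rank correlation, per (condition, time) cell, between node mean log2 level
and node protein count, with average-rank ties and a two-sided p-value from
the t-approximation ($t = \rho\sqrt{(n-2)/(1-\rho^2)}$); for $n \le 10$
without ties an exact mode is available. Both the all-nodes and
secreting-nodes-only variants are exposed.

# The synthetic-data generator

`generate_dataset()` emulates the study conditions the pipeline assumes —
4 substrates (one control) × 3 replicates × 2 time points — and returns the
four input tables plus a truth object for recovery testing. Defaults, fixed
once as realistic for this data type:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 2000 | desk-scale universe (full study: ~11,000) |
| `n_blocks`, `block_size` | 8, 40 | planted co-regulated modules |
| `baseline_mean`, `baseline_sd` | 7, 2 | log2 baseline, marginally Normal |
| `block_level_sd` | 0.8 | within-block baseline sd (see below) |
| `nb_dispersion` | 0.05 | NB $\alpha$, variance $\mu + \alpha\mu^2$ (bulk RNA-seq scale) |
| `effect_size` | 4 | planted log2 induction of block genes |
| `term_coverage` | 0.6 | fraction of block genes carrying the planted term |
| `coupling` | 2 | logistic slope, log2 level → detection probability |
| `secretable_fraction` | 0.15 | non-block genes that can ever be detected |
| `n_background_proteins` | 25 | control-condition background proteins |

Counts are negative-binomial around size-factor-scaled means (per-sample
factors LogNormal(0, 0.15)). Each block is induced (`effect_size` log2
units) on a random non-empty subset of the non-control substrates, with
block-specific time-point amplitudes (uniform 0.7–1.3×) mimicking early-
versus late-responding modules. Block genes share a baseline level
component: baselines are Normal(block mean, 0.8) with block means drawn so
the gene-level marginal stays exactly Normal(7, 2). Both choices reflect
that a co-regulated module is coherent in level *and* shape — on an
absolute-level map, a "block" of genes scattered across 8 log2 units of
baseline is not a recoverable pattern, and treating it as one would make
recovery tests meaningless.

Protein detection is Bernoulli with probability
$\operatorname{logistic}(2\,(\ell - \tau))$ where $\ell$ is the true log2
level and $\tau$ the 80th percentile of baselines, restricted to the
secretable subset (all block genes plus 15% of background genes),
emulating the signal-peptide fraction of a proteome. Detected entries get
1 + Poisson(4) spectra. A disjoint background set is detected in control
samples and is removed by background subtraction downstream. At these
defaults the node-level Spearman correlation lands around 0.3–0.45, the
scale reported for real fungal transcriptome–secretome data.

What the generator does **not** emulate: gene length and GC biases,
mean-dependent dispersion trends, annotation term hierarchies (GO
ancestors), correlated background annotation, protein-level abundance
biases of spectral counting (length, ionization), and batch structure.
Passing recovery tests therefore demonstrates the pipeline's statistical
machinery, not robustness to these real-data artifacts.

# Numerical conventions and edge cases

* Quantiles: `type = 4` (empirical cdf, linear interpolation) for the SOM
  initial radius; `type = 7` (R default) for hotspot and responsive-level
  percentiles. All selection comparisons are strict (`>`).
* BMU ties break toward the lowest node id; node ids are row-major,
  1-based.
* Empty nodes carry `NA` means and are excluded from pooled percentiles;
  constant vectors make Spearman's rho undefined (`NA`), not an error.
* Welch test with zero variance in both groups: p = 1 when the means agree
  (identical replicates carry no evidence), 0 otherwise.
* The hypergeometric tail rejects infeasible $(k, n, K, N)$ outright; the
  implementation is validated against exhaustive `choose()` enumeration for
  every feasible input with $N \le 60$ (max |Δ| < 1e-12).
* All stochastic steps (generator, SOM initialization, permutation tests)
  take explicit seeds and are bit-reproducible.

# Problem sizes used in the test suite

Unit examples run on toy fixtures (3–200 genes). Recovery tests use the
generator's default 2000-gene, 8-block design over 20 seeds for each of the
planted and null conditions, with a 77-node map (11 × 7 from the 25
genes-per-node rule) trained for 39 batch epochs; the whole suite completes
in well under a minute on one core. The full-scale 24 × 19 / 456,000-
presentation configuration is exercised arithmetically (planning, epoch
conversion) rather than trained in tests.

# Known limitations

* **Screened enrichment family.** Admitting only terms with ≥ 3 in-node
  occurrences before BH makes the adjusted p-values anti-conservative under
  a complete null: roughly a quarter of null simulations produce at least
  one false (node, term) pair at FDR < 0.01, each a genuine random clump
  (e.g. 4 of 24 term carriers landing in one node). The false-call *rate*
  over all node × term hypotheses stays far below the nominal level
  (~2 × 10⁻⁴ measured). Treat single isolated enrichment calls with
  caution; planted-signal calls are orders of magnitude stronger.
* The Welch screen on log2 values is less powerful than a count GLM at low
  counts; it is a screen, not the basis of node selection.
* The SOM neighbourhood (cut Gaussian, linear radius decay, uniform
  initialization) is one defensible convention; cluster *memberships* near
  node boundaries can differ between conventions even though the package's
  invariants (determinism, non-increasing quantization error, spatial
  coherence of true blocks) hold regardless.
* With two time points the "time course" is a pair of snapshots; no
  temporal model is fitted.
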