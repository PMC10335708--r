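---
title: "Multi-reference ensemble annotation with unseen-type detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-reference ensemble annotation with unseen-type detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensembleAnnot)
```

## The problem

Reference-based cell-type annotation transfers labels from a well-annotated
scRNA-seq atlas to a new query dataset. Two things routinely go wrong.
First, the choice of reference matters: different atlases carry different
technical noise, different label curation, and different informative genes,
and no single choice of reference or of gene-selection statistic dominates.
Second, the query usually contains cell types that no reference carries —
*unseen* types. A classifier trained only on reference types will
confidently mislabel those cells unless the method can abstain.

ensembleAnnot addresses both at once. Instead of merging references into one
atlas (which requires batch correction and risks over-correction), it keeps
every reference separate and builds an ensemble over *views*: each of $M$
references is examined through 8 gene-selection lenses, giving $8M$
reference subsets, each of which trains its own small classifier. Query
cells are labeled by a normalized vote across all base models, and a
per-cell uncertainty score — high exactly when the base models are
individually unsure, collectively unsure, or mutually inconsistent — drives
an adaptive rejection rule that labels putative unseen-type cells
`"unassigned"`.

## The pipeline

### Preprocessing

Each dataset is library-size normalized (each cell scaled to a total of
10{,}000), and — *after* gene selection — log-transformed
($\log_2(x+1)$), z-scored per gene (population SD; constant genes map to
0), and min-max scaled per gene to $[0,1]$ (constant genes map to 0). The
container enforces this ordering as a stage machine
(`raw -> libnorm -> selected -> log -> zscore -> minmax`); applying a step
out of order is an error, not a silent recompute. Reference and query
matrices are each scaled on their own cells: the query must be usable
without refitting reference statistics, and per-dataset scaling is the only
self-contained choice.

Optional curation filters mirror common practice for reference collections:
drop cell types with fewer than 10 cells, then genes detected in fewer than
100 cells, then cells expressing fewer than 100 genes, in that order.

### Gene selection: eight views

Five supervised statistics are computed one-vs-rest per cell type on
log-normalized data and aggregated by the maximum over types (markers are
type-specific, so a gene's best contrast is what matters):

* **DE** — moderated $t$ (limma's empirical-Bayes shrinkage);
* **DV** — Bartlett's variance-homogeneity statistic;
* **DD** — two-sample Kolmogorov–Smirnov statistic;
* **DP** — Pearson $\chi^2$ on the 2×2 detection table (expressed vs not);
* **BI** — bimodality index $\delta\sqrt{\pi(1-\pi)}$, with the
  two-component split found by exact 1-D two-means and $\delta$ the
  pooled-SD-standardized mean separation.

Three unsupervised highly-variable-gene recipes run on library-normalized
data: **GC** (Gini coefficient), **Disp** (variance/mean, z-scored within
20 mean bins), and **Vst** (standardized variance after a loess
mean–variance fit, standardized values clipped at $\sqrt{n}$).

Each method keeps its top `n_top` genes (default 500, a common HVG scale; a
score-threshold mode is also available), which are then intersected with
the query's gene namespace (exact string match; no alias resolution).
Subsets with fewer than 10 surviving genes are dropped from the ensemble
entirely — from both the vote and its normalizer.

The eight statistics are deliberately non-interchangeable, and our
synthetic studies make their trade-offs concrete. In shallow,
zero-inflated count data, mean/variance/distribution contrasts (DE, DV,
DD) recover planted markers reliably, but BI is dominated by the
zeros-vs-detected split that *every* sparse gene exhibits, and DP cannot
see markers that sit on genes already detected in all cells. In deeply
sequenced data the situation reverses: detection saturates (hurting DP)
while bimodality becomes type-driven and BI ranks markers highly. No
single view wins everywhere — which is precisely why the ensemble uses all
eight.

### Base classifiers

Each subset trains an autoencoder-regularized classifier: a two-layer ReLU
encoder (default widths 256 then 64), a linear softmax head over the
*global* cell-type vocabulary $K$ (the union over all references, ordered
lexicographically), and a mirrored decoder. The loss is

$$\mathcal{L} = \mathcal{L}_{ce} + \lambda\,\mathcal{L}_{re},\qquad
\lambda = 1\ \text{by default},$$

where $\mathcal{L}_{ce}$ is the mean cross-entropy (natural log) over
reference cells and $\mathcal{L}_{re}$ is the mean squared reconstruction
error over *both* reference and query cells. Query cells thus shape the
embedding — letting it adapt to the query batch — without ever receiving
pseudo-labels. Training uses Adam (learning rate $10^{-3}$) on shuffled
minibatches (default 128) mixing reference and query rows, for a default
30 epochs. Setting $\lambda = 0$ recovers a plain classifier.

Design notes:

* The head always spans the global vocabulary, including types absent from
  the subset's reference; those columns receive no supervision and their
  softmax mass is down-weighted later by the vote normalizer.
* Everything is seeded: one master seed, per-model seed = master + subset
  index; identical configuration reproduces parameters bitwise. For this
  reason the classifier uses no dropout by default (a `dropout`-free path
  keeps the determinism contract simple at these model sizes).
* The networks are intentionally small and are implemented directly on
  BLAS-backed matrix operations with hand-derived gradients; per-epoch
  cross-entropy, reconstruction, and total losses are logged, and a
  non-finite loss aborts with diagnostics rather than propagating NaNs.

### Voting

Each model votes its argmax label (ties to the lowest vocabulary index).
Cell $c$'s consensus label maximizes
$\sum_{ij} \mathbf{1}[\hat{Y}^{ij}_c = k] / L_k$, where $L_k$ counts the
retained subsets whose reference carries type $k$. The normalization is
what keeps rare, single-reference types alive: a type carried by one
reference can collect at most $8$ raw votes against $8M$ for ubiquitous
types, so raw majority voting would extinguish it. When every $L_k$ is
equal the rule provably reduces to plain majority voting.

### Uncertainty: three complementary entropies

All three metrics use base-2 entropy ($0\log 0 = 0$):

* $m^{(1)}$ (intra-model): mean over models of the entropy of the model's
  predicted probability row — high when individual classifiers are unsure;
* $m^{(2)}$ (inter-model): entropy of the row-normalized
  $L_k$-weighted *average probability* profile — high when the pool as a
  whole backs no type;
* $m^{(3)}$ (inter-prediction): entropy of the row-normalized
  $L_k$-weighted *vote count* profile — high when models disagree.

Each metric is min-max scaled over query cells (a constant metric scales
to zeros rather than 0/0), and the ensemble score $m$ is their mean, so
$m \in [0,1]$. The three are genuinely complementary: unanimous one-hot
predictions give $m^{(1)}=m^{(2)}=m^{(3)}=0$, but confidently
*disagreeing* models give $m^{(1)} = 0$ with $m^{(3)}$ large, and a pool
of individually-vague models that agree on the argmax gives $m^{(3)} = 0$
with $m^{(1)}$ large.

### Adaptive threshold

When the query contains unseen types, $m$ is expected to be a mixture:
shared-type cells mass at low $m$, unseen-type cells at high $m$. A 1-D
Gaussian mixture is fitted to $m$ by EM for $k = 1,\dots,5$ components and
the count is chosen by AIC with $3k-1$ free parameters. Numerical choices:
10 seeded restarts per $k$ (1-D EM is restart-sensitive), a variance floor
of $10^{-6}$ (prevents single-point collapse), log-sum-exp responsibility
updates, and a failed restart (empty component) is simply discarded.

If AIC selects one component, no cell is flagged. Otherwise cells go to
their maximum-posterior component (ties to the larger-mean component), and
the *uncertain groups* are the groups with mean $m \ge 0.6$ together
with — unconditionally — the largest-mean group. We read the largest-mean
rule as unconditional because the rejection decision must not evaporate
merely because all group means sit below the cutoff while the mixture is
clearly multimodal; a `strict_cutoff_only` switch provides the other
reading. All member cells of uncertain groups become `"unassigned"`.

## The synthetic generator

`simulate_collection()` emulates the statistical structure the method
assumes, not any particular platform: negative-binomial counts (fixed
dispersion 0.3, the scale typical of UMI data), log-normal baseline gene
means (`baseline_log_mean`, default 0.5, a shallow droplet-like depth),
disjoint blocks of `n_markers_per_type` markers (default 30) elevated by
`marker_effect` (default 2 on the natural-log scale, roughly 7.4-fold),
per-(batch, gene) log-normal batch factors (`batch_shift_sd`, default
0.15), and uniform zero-inflation (`dropout_rate`, default 0.2). The query
is always its own batch; when an `unseen_type` is set it is withheld from
every reference and injected into the query at `unseen_fraction`.

The default study used throughout the tests is 3 references × 5 global
types × 100 cells/type over 2000 genes, with a query of 60 cells per
shared type, so holding out one type gives an unseen fraction of exactly
0.2. The generator does *not* emulate gene–gene correlation modules,
expression-dependent dropout, cell-size covariates, doublets, or ambient
RNA; passing tests therefore demonstrate internal correctness of the
method and recoverability under its own assumptions, not performance on
any real tissue.

## What the tests establish

The suite checks, among others: exact (1e-10) agreement of every formula —
entropies, pooled profiles, the normalized vote, both losses, AUPRC / F1 /
accuracy / accuracy-ratio — with independent brute-force loop oracles;
the reduction identities (equal $L_k$ ⇒ plain majority, unanimous one-hot
⇒ zero uncertainty, $\lambda = 0$ ⇒ pure cross-entropy); the EM fit
against `mclust` on separated data; and end-to-end leave-one-type-out
recovery on the default study at scaled-down training settings
(hidden widths 64/32, 40 epochs, learning rate $3 \times 10^{-3}$ — sizes
chosen so a study runs in about a minute on one core). Benchmark-scale
runs at unseen fractions 0.05–0.2 back the proportion-recovery property
of the adaptive threshold, and a deliberately *heterogeneous* grid of
24 smaller studies (2–3 references × 4 types, 800 genes, hidden 32/16)
— varying sequencing depth, dropout, batch shift, marker
strength and reference count — backs the metric-complementarity property.
The heterogeneity is essential, not decorative: within a single regime one
uncertainty metric can dominate every run, and an average can never beat
its best component in pairwise wins; the complementarity of the three
metrics shows up exactly when test conditions span different data regimes,
which is how multi-technology benchmark collections behave.

## Known limitations

* Cell-type name harmonization across references is the user's job (a
  two-column rename map is applied before the vocabulary is built); there
  is no ontology-aware matching.
* `"unassigned"` cells receive no further characterization (no clustering
  or novel-type naming).
* References are never batch-corrected against each other by design; the
  ensemble is the integration mechanism.
* HDF5 containers are not read directly; convert to MTX or CSV/TSV.
* The min-max scaling of the uncertainty metrics is per-query-dataset, so
  $m$ values are comparable within one query but not across queries.
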