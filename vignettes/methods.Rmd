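---
title: "From UMI counts to programming-factor candidates: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From UMI counts to programming-factor candidates: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfscout)
```

# Scope and model

`tfscout` takes a gene × barcode UMI count matrix (with per-barcode batch
labels) to ranked, cluster-specific transcription-factor candidates, and
additionally implements the two pieces of quantification math used to verify
such candidates at the bench: Xo-method lentiviral titering and
2^−ΔΔCt expression analysis.  Everything upstream of the count matrix (read
alignment, cell calling) and everything downstream of the candidate list
(literature triage, cloning, differentiation) is out of scope.

The statistical backbone is deliberately conventional for droplet-based
single-cell data:

* **Counts** are treated as overdispersed (negative-binomial-like) UMI
  counts; *detection* of a gene in a cell means ≥ 1 UMI.
* **Library size** is a nuisance: values are per-cell scaled to a fixed
  pseudo-library and log1p-transformed before any distance or test.
* **Batch effects** are approximately multiplicative per gene, hence
  approximately additive in log space and removable as shifts in PCA space —
  the regime mutual-nearest-neighbor (MNN) correction is designed for.
* **Cluster identity** is discrete and shared across batches.

# Quality control

**Empty droplets.** A barcode with total UMIs strictly below
`empty_umi_threshold = 50` is called an empty droplet.  The boundary is
strict: a 50-UMI barcode is kept.  Nothing model-based (no ambient-profile
test) is attempted — the rule's simplicity is the point, and the synthetic
generator plants empties strictly inside its domain (5–45 UMIs).

**Ambient genes.** A gene whose counts in empty droplets exceed
`ambient_fraction_threshold = 0.30` of its total counts (strictly above) is
flagged ambient and barred from the variable-gene list.  It is *not* removed
from the matrix: ambient genes still contribute to library sizes and tests,
they just cannot drive the embedding.  Genes with zero total count are never
flagged.

**Marker gating.** Unwanted cell classes are removed per cell: a barcode is
dropped when ≥ `min_detected` genes of any one gating set (e.g. hemoglobin
subunits; PDGFRB/PECAM1) are detected.  Whether the original analysis gated
per cell or removed whole clusters is not documented; per-cell gating is the
default here because it does not depend on a clustering that has not happened
yet, and cluster-level removal remains available by subsetting on cluster
labels afterwards.

# Normalization and variable genes

`log_normalize()` computes `ln(1 + s·x/τ)` with scale factor `s = 10,000`
and per-cell total `τ`; zeros map to exactly zero, so sparsity is preserved,
and `sum(expm1(values))` per cell equals `s` (a conservation identity the
tests exploit).  Natural log and `s = 10,000` are the conventions of the
standard single-cell toolchains; both are configurable.

`decompose_variance()` fits a smooth trend of per-gene variance on per-gene
mean across genes (robust local regression, `span = 0.5`, symmetric family)
and calls the trend value at a gene's mean its *technical* variance; the
residual `biological = total − technical` (exactly, by construction) ranks
genes.  With fewer than 30 genes the trend degenerates to a straight line —
the smallest monotone smooth — because a local fit is meaningless at that
size.  Ambient genes and genes with non-positive biological variance are
never selected.  The trend is purely empirical; no error model
(Poisson/spike-in) is assumed.

# PCA and batch correction

PCA is computed on the gene-centered HVG submatrix; `n_pcs = 50` follows
common practice for datasets of this complexity, and the function truncates
(with a warning) at the rank bound.  Correction operates on
cosine-normalized coordinates (scale invariance; standard MNN practice).
Batches merge largest-first by default — the biggest batch is the most
stable reference — and the reference coordinates are never moved.

For each merge, mutual k-nearest-neighbor pairs (`k_mnn = 20`) define
correction vectors (reference minus incoming), and each incoming cell is
shifted by a Gaussian-kernel-weighted average of pair vectors, the kernel
bandwidth defaulting to the median pair-vector length.  One detail was
settled empirically: a *single* such sweep removes only ~50–65% of a planted
constant offset, because nearest-neighbor pairs concentrate on the facing
edges of the two point clouds and shrink the estimated magnitude (the
estimated *direction* is essentially exact — cosine ≈ 0.999 against the true
offset in our experiments).  The correction is therefore iterated: pairs are
re-found on the partially corrected coordinates and the shift reapplied, up
to `max_iter = 10` sweeps or until the median pair vector falls below 1% of
its initial length.  Convergence is geometric; with realistic cluster spread
this removes ≥ 90% of a planted offset, which is the property the test suite
enforces.  No claim of numerical equivalence with any released MNN
implementation is made.

A caveat on cosine normalization: a point cloud straddling the origin has no
well-defined direction, so embeddings should not place a cluster at zero.
PCA output never does (cells are spread around the origin but clusters are
not centered on it in all components simultaneously); hand-made embeddings
used in tests keep centers away from the origin for this reason.

# Clustering and cell cycle

The SNN graph connects cells by the Jaccard overlap of their neighborhoods
(self plus `k_neighbors = 20` nearest cells, Euclidean metric, distance ties
broken by cell index).  Edges with weight ≤ `prune_jaccard = 1/15` are
removed — both defaults are the standard toolchain's, as the original
analysis states only the resolution parameter.  Louvain community detection
(igraph's multi-level implementation) maximizes resolution-scaled modularity;
resolutions of 1.0–1.6 are typical, with higher values giving finer
partitions (a property the tests check).  Labels are relabeled contiguously
from 0, largest cluster first; an edgeless graph yields singletons with a
warning rather than an error.

Cell-cycle scoring is the binned control-gene scheme: genes are binned into
`n_bins = 25` by mean expression, each S/G2M program gene contributes
`n_ctrl = 50` controls sampled from its bin (seeded), and a cell's phase
score is mean(program) − mean(controls).  Phase is the arg-max of (S, G2M)
when positive, else G1 (G1 and G0 being indistinguishable transcriptomically);
an exact positive tie goes to G2M — an arbitrary but documented and
deterministic choice.  The shipped S/G2M lists are the standard human
scoring lists; for non-human data they act through exact uppercased symbol
matches, which is a stated substitution, not an ortholog inference.

# Marker and TF statistics

The F1 marker score is pure detection counting: TP/FP/FN/TN over all cells
for each (gene, cluster), precision, recall and their harmonic mean, with
the 0/0 convention that precision, recall and F1 are 0 when their
denominators vanish (the formulas are undefined there).  Ties in F1 are
broken by precision, then symbol, so output order is total and reproducible.

Differential expression is the two-sided Wilcoxon rank-sum test of one
cluster against all remaining cells, restricted to genes detected in at
least `min_pct = 0.25` of either group.  p-values use exhaustive permutation
enumeration when both groups have ≤ 8 observations (exact under ties) and a
tie-corrected normal approximation (no continuity correction) otherwise; a
gene constant across all cells gets p = 1 and logFC = 0.  The effect size is
the natural-log ratio of de-logged group means with pseudocount 1 — the
v2-era convention of the standard toolchain — and Bonferroni adjustment is
applied over the tested genes, that toolchain's default, since no multiple-
testing procedure is documented for this step.

TF candidates are differential genes whose symbols *perfectly* match a
checklist entry (exact string equality after uppercasing — no prefix or
fuzzy matching, so FOXP1L never matches FOXP1), ranked by raw signed
avg_logFC descending and truncated at `top_n = 20`.  Raw rather than
absolute logFC is used because candidates are meant for *overexpression*:
only enrichment is of interest.

# Projection onto a reference

Reference features are ranked by the residual of log dropout rate regressed
on log mean expression (genes dropping out more than their abundance
predicts are informative); `n_features` of 2000–2500 are typical.  Cluster
centroids are per-gene *medians* (robust to outlier cells).  Each query cell
computes cosine, Pearson and Spearman similarity to every centroid over the
shared features (optionally through a user-supplied two-column ortholog map;
default identity); each measure votes for its arg-max, and the cell is
assigned when ≥ `consensus_min_agree = 2` measures agree *and* the winning
centroid's best similarity reaches `similarity_threshold = 0.7`.  Setting
the threshold to 0 disables similarity-based rejection but not the consensus
requirement; a three-way split (or any tie for the top vote) is always
"unassigned".  Fewer than 10 shared features is an error — a projection on
less is noise.

# Wet-lab quantification

The Xo transform `xo = E^(−Ct)` linearizes qPCR quantification cycles; the
amplification efficiency E defaults to 2 (perfect doubling) and is exposed
because the source procedure does not state it.  Titration fits regress
**volume on relative copy number** — this orientation is forced by the
definition `VPD = a·(relative copy of reference) + b`, which maps a copy
number to a volume — using the mean of replicate Xo values (not of Ct
values) for LV2 and β-actin.  `compute_titer()` then applies
`titer = cells·MOI/VPD`, so `titer·VPD = cells·MOI` holds exactly on every
output.  A non-positive VPD (extrapolation failure) is an error, not a
number.

ΔΔCt analysis normalizes each sample's target Ct to its housekeeping mean,
then to a designated reference sample; `fold = 2^(−ΔΔCt)`, and the reference
sample's own fold is exactly 1.  The SD is computed over replicate-level
fold changes (the alternative — analytic error propagation — is not
documented in the source procedure; the replicate-level choice is flagged).
Welch's t-test uses the textbook statistic and Welch–Satterthwaite degrees
of freedom; two zero-variance groups with equal means give p = 1 by
convention.

# The synthetic world

`simulate_counts()` draws negative-binomial counts
(`Var = μ + φμ²`, `φ = nb_dispersion = 0.5`) with:

* a log-normal base expression profile and log-normal library sizes
  (mean 5,000 UMIs, CV ≈ 0.3);
* `n_clusters = 4` planted clusters of 500 cells each, with 20 disjoint
  marker genes per cluster elevated `marker_fold_change = 4`-fold in
  expectation, half of them labelled TFs (all planted TFs are planted
  markers of the same cluster);
* per-(gene, batch) log-normal multiplicative factors
  (`batch_effect_sd = 0.15` on the log scale, batches balanced within
  clusters so batch never confounds cluster);
* an ambient pool (5% of genes, expressed ~50× lower in real cells) from
  which 200 empty droplets draw multinomial profiles with 5–45 total UMIs —
  so the <50-UMI rule and the >30% ambient rule are discoverable by
  construction;
* 40-gene S and G2M programs boosted 5-fold in two disjoint 10% subsets of
  cells;
* a TF checklist containing every planted TF plus broadly expressed decoys.

Each sub-generator draws from its own seed stream derived from the master
seed (`sub_seed()`), so adding a feature never perturbs earlier draws, and
identical configs give byte-identical output.  The generator emulates the
*statistical structure* the pipeline assumes — overdispersion, batch shifts,
ambient sharing, planted enrichment — and nothing else: no pathway
correlation structure, no doublets, no spliced/unspliced layers, no
cluster-specific library sizes.  A green recovery test therefore establishes
that the pipeline recovers structure *of the kind it models*, not that it is
robust to everything real tissue does.

`simulate_qpcr()` builds Ct tables from
`Ct = Ct_ref − log_E(relative quantity) + noise`, with target genes sitting
a fixed 3 cycles above the housekeeping gene in the reference sample (any
constant cancels in ΔΔCt) and a titration whose LV2/β-actin copy number is
linear in volume with the proportionality fixed by the true titer through
the VPD identity — so at zero noise the downstream fit recovers the planted
titer and fold changes exactly, which the tests assert.

# Numerical conventions, in one place

* Strict thresholds: `< 50` UMIs (empty), `> 30%` (ambient), `≤ prune`
  (SNN edge removal), `≥ min_pct` (DE filter).
* All symbol matching is exact after uppercasing.
* Deterministic tie-breaks everywhere: distance ties by cell index, F1 ties
  by precision then symbol, logFC ties by symbol, S/G2M score tie → G2M,
  top-vote tie → unassigned.
* Degenerate inputs are errors when silent answers would mislead (zero-count
  cells, empty clusters, < 2 titration points, VPD ≤ 0, < 10 shared
  features) and conventions when they are well-defined limits (0/0 → 0 for
  F1; constant gene → p = 1; two-point regression → R² = 1).
* Seeds: every stochastic stage takes or derives an explicit seed; the
  pipeline fans a master seed out per stage.

# Known limitations

* Louvain is delegated to igraph; per-pass modularity is not observable,
  and label stability under cell permutation is only guaranteed up to the
  usual Louvain order sensitivity (determinism under identical input and
  seed *is* guaranteed and tested).
* MNN correction assumes shared populations across batches; a cell type
  private to one batch will be dragged toward its nearest shared neighbors.
* The variance trend is empirical; with very few genes the technical
  component is only a straight-line proxy.
* Projection consensus is cluster-level only; no per-cell nearest-neighbor
  projection mode is provided.
* The 2-D plotting embedding (`embed_2d()`) is plumbing and carries no
  guarantees; nothing downstream depends on it.
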