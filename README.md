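# tfscout

**Cluster-specific transcription-factor discovery from single-cell UMI
counts, plus the quantification math that validates the candidates at the
bench.**

## The problem

Forward programming turns pluripotent stem cells into a target neuron type by
overexpressing the transcription factors (TFs) that define that type.  The
hard part is picking the factors.  Given a single-cell RNA-seq survey of the
tissue where the target cell type lives — for example the medial entorhinal
cortex, whose Reelin-expressing stellate cells are of particular interest for
early Alzheimer's disease — the candidates are the TFs most specifically
enriched in the target cell cluster.  `tfscout` implements that computation
as a tested, reusable pipeline:

1. **Quality control** — empty droplets are barcodes with total UMIs < 50;
   a gene is *ambient* when > 30% of its counts sit in empty droplets and is
   barred from the variable-gene list; unwanted cell classes (red blood
   cells, vascular cells) are removed by marker gating.
2. **Normalization** — per-cell scaling to 10,000 counts and `log1p`;
   highly variable genes by decomposing per-gene variance into a smooth
   mean–variance trend (technical) plus a residual (biological).
3. **Integration** — PCA on the HVGs (50 components by default) and
   mutual-nearest-neighbor (MNN) batch correction of the coordinates.
4. **Clustering** — shared-nearest-neighbor graph (Jaccard weights, pruned
   at 1/15) and Louvain community detection with a resolution parameter;
   cell-cycle S/G2M/G1 phases by binned control-gene module scores.
5. **Marker statistics** — for gene *g* and cluster *c*, detection
   (≥ 1 UMI) gives TP/FP/FN/TN over cells, and

   `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
   `F1 = 2·P·R/(P+R)`

   ranks cluster markers by F1.  Differential expression uses the two-sided
   Wilcoxon rank-sum test (genes detected in ≥ 25% of either group), with
   `avg_logFC = ln[(mean(expm1 x_in)+1)/(mean(expm1 x_out)+1)]` and
   Bonferroni adjustment.
6. **TF selection** — candidates are genes whose symbols perfectly match a
   curated checklist of DNA-binding RNA-polymerase-II TFs; the top 20 by
   avg_logFC are reported per cluster.
7. **Projection** — query cells are assigned to reference cluster centroids
   (per-gene medians) by the consensus of cosine, Pearson and Spearman
   similarities (2-of-3 agreement, similarity ≥ 0.7 by default).
8. **Wet-lab math** — lentiviral titering by the Xo method
   (`xo = E^(−Ct)`; standard curve of volume on LV2/β-actin relative copy
   number; `VPD = a·copy_ref + b`; `titer = cells·MOI/VPD`), and qPCR
   relative expression by `2^(−ΔΔCt)` with Welch's unequal-variance t-test.

A synthetic-data module (`simulate_counts()`, `simulate_qpcr()`) generates
multi-batch negative-binomial counts with planted clusters, markers, TFs,
ambient contamination, empty droplets and cell-cycle programs — with the
ground truth returned alongside — so the entire pipeline is exercisable and
testable offline.

## Worked example

```r
library(tfscout)

sim <- simulate_counts(sim_config(n_genes = 1000, n_cells_per_cluster = 300,
                                  n_clusters = 3, marker_fold_change = 5,
                                  n_empty_droplets = 150, seed = 42))
cfg <- pipeline_config(counts = sim$counts,
                       tf_checklist = sim$truth$tf_checklist,
                       s_genes = sim$truth$s_genes,
                       g2m_genes = sim$truth$g2m_genes,
                       qc = qc_params(n_hvgs = 300),
                       clustering = cluster_params(resolution = 1.0),
                       n_pcs = 30, seed = 42, out_dir = "demo_run")
report <- run_pipeline(cfg)
```

This prints (abridged):

```
barcodes: 1050  empties: 150  ambient genes: 48
cells retained: 900
ClusterAssignment: 900 cells in 8 clusters (modularity 0.776, resolution 1)
  rank   gene avg_logfc   adjusted_p    pct_in   pct_out
1    1 G00380  1.373057 7.962198e-71 0.9960159 0.9445300
2    2 G00183  1.367715 1.702862e-75 1.0000000 0.9907550
3    3 G00118  1.305620 2.403087e-59 0.9721116 0.7812018
```

All 150 planted empty droplets are flagged, the planted ambient genes are
barred from HVG selection, and every planted TF of the first ground-truth
cluster appears in the matching cluster's top-20 candidate list (recovery
1.0 in this run).  `demo_run/` holds per-stage TSVs plus `manifest.json`
with parameters, seed and versions; rerunning the same config reproduces
byte-identical tables.

The titering math, on a simulated titration with 0.1-cycle Ct noise and a
true titer of 2 × 10⁴ U/µl:

```r
q   <- simulate_qpcr(qpcr_sim_config(ct_noise_sd = 0.1, true_titer = 2e4, seed = 42))
fit <- fit_titration_curve(q$titration_table)
res <- compute_titer(fit, q$ref_relative_copy, n_cells = 1e5, moi = 10)
```

```
TitrationFit: volume = 51.58 * copy + 0.1401 (R^2 = 0.997, 5 points)
VPD = 51.72 ul, titer = 19333 U/ul
```

i.e. a 3% titer error at that noise level, and exact recovery at zero noise
(`titer · VPD ≡ cells · MOI` always holds algebraically).

## Command line

```sh
Rscript inst/cli/tfscout.R simulate --out-dir data --seed 1
Rscript inst/cli/tfscout.R run --counts data --tf-checklist inst/extdata/tf_checklist_demo.txt \
    --resolution 1.6 --n-hvgs 1000 --out-dir out
Rscript inst/cli/tfscout.R titer --ct-table titration.csv --ref-copy 1 --cells 1e5 --moi 10
Rscript inst/cli/tfscout.R ddct --ct-table ct.csv --reference-sample ipsc
```

## Further reading

The methods vignette (`vignettes/methods.Rmd`) documents the model
assumptions, every tunable parameter with its default and rationale, what
the synthetic generator does and does not emulate, and the numerical
choices (tie-breaks, degenerate inputs, tolerances).
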