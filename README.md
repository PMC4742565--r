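# thrombotraj

Single-cell pseudotime trajectory analysis of zebrafish thrombocyte
differentiation.

## The problem

Zebrafish thrombocytes (the nucleated fish analog of mammalian platelets)
mature in the kidney marrow along a continuous differentiation path, from
hematopoietic stem cells through committed progenitors to mature cells.
Plate-based single-cell RNA-seq of index-sorted `cd41:EGFP` reporter cells
captures a snapshot of that continuum: each cell carries its transcriptome
plus the fluorescence, size (FSC) and granularity (SSC) recorded at the
sorter. `thrombotraj` reconstructs the differentiation ordering from such
data and analyses what changes along it. It is aimed at analysts working
with TPM-scale expression matrices from sorted plates with ERCC spike-ins.

## What the package computes

**QC and normalization.** Cells with fewer than a minimum number of paired
reads or expressed genes (TPM > 1) are excluded; spike-in transcripts are
stripped and every cell is rescaled so its endogenous TPM values sum to
10^6; genes above 1 TPM in fewer than 3 cells are dropped. The ratio of
endogenous to spike-in signal provides a per-cell mRNA-content proxy.

**ICA-composite pseudotime.** Independent component analysis (FastICA,
logcosh contrast) of standardized log(TPM+1) values yields K = 4 latent
factors over cells, chosen at the elbow of the rank-k reconstruction
error. Factors are sign-oriented so that higher values track higher
reporter fluorescence, and take on the roles seen in this experimental
design: progression within the EGFP-low population, the low-to-high
switch, progression within the EGFP-high population, and an outlier
factor flagging a few aberrant high-FSC/SSC cells. Ward clustering in
factor space partitions the cells into six clusters, labeled
`1a, 1b, 2, 3, 4` by fluorescence plus an `outlier` cluster; cells are
then ranked by stage and, within each stage, by the factor that explains
that stage's variability. The resulting rank is the pseudotime.

**GPLVM cross-validation.** An independent one-dimensional Gaussian-process
latent variable model (MAP over latent coordinates and RBF-kernel
hyperparameters, exact marginal likelihood, standard-normal latent prior,
principal-coordinate initialization, best of several restarts) re-orders
the same cells without using fluorescence. Agreement between the two
orderings is summarized as |Spearman rho|.

**Markers and dynamics.** Cluster markers are ranked by one-vs-rest
randomized-tree Gini importance. Pseudotime-dynamic genes are detected by
comparing, per gene, an RBF-kernel GP (expression may change along
pseudotime) with a constant-kernel GP (it may not) via their maximized
log marginal likelihoods; flagged genes are clustered on standardized
posterior-mean curves into three trend groups: transient (up then down,
group I), declining (group II), and switch-on-and-maintain (group III).
Two cell groups can be compared per gene by a Gaussian likelihood-ratio
test with Holm-Šidák multiple-testing correction
(adjusted p = 1 − (1 − p)^k, step-down).

**Ohnolog classification.** Duplicate gene pairs retained from the teleost
whole-genome duplication are classified from binarized expression
(TPM > 1) into NotExpressed, XOR (mutually exclusive usage, large
`both_min_diff` = min(cells using only one member) − cells using both),
Single (one member dominates) and Mixed, via a fixed decision tree with
thresholds 300/15/60 (rescalable to the dataset size).

**Synthetic data.** `generate_dataset()` produces matrices with known
ground truth — a five-state continuum, bimodal fluorescence, monotone
markers, the three trend groups, declining mRNA content and expressed-gene
count, spike-ins, dropout, and planted ohnolog classes — so that every
stage of the pipeline is testable end to end.

## Worked example

```r
library(thrombotraj)

params <- generator_params(n_cells = 110, n_genes = 220, n_markers = 6,
                           n_group1 = 15, n_group2 = 15, n_group3 = 15,
                           n_outlier_genes = 12, n_ohnolog_pairs_per_class = 3,
                           n_spikeins = 10)
ds <- generate_dataset(params)
cfg <- pipeline_config(qc = qc_thresholds(min_genes = 50),
                       dynamic_max_genes = 60, marker_trees = 300)
report <- run_pipeline(ds$matrix, ds$metadata, cfg,
                       ohnolog_pairs = ds$truth$ohnolog_pairs)
print(report)
```

```
Pipeline report
  cells retained:      111
  genes retained:      214
  ordering agreement:  0.940 (|Spearman|, ICA vs GPLVM)
  dynamic genes:       28
  ohnolog classes:     NotExpressed=3, XOR=3, Single=3, Mixed=3
```

All 111 simulated cells pass QC and 214 of 230 genes survive the
prevalence filter. The ICA-composite and GPLVM pseudotimes agree at
|rho| = 0.94 on this small plate (agreement tightens with more cells).
28 genes exceed the dynamic-gene likelihood-ratio threshold, and the
twelve planted ohnolog pairs are recovered in their four classes, three
pairs each. Per-cluster marker rankings are in `report$markers`; e.g.
`head(report$markers[["4"]]$ranking, 3)` lists the genes that best
separate the mature cluster, led by the planted cd41-like marker
(`gene_0001`, importance 0.037).

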