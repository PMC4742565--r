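---
title: "Models and methods behind thrombotraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thrombotraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(thrombotraj)
```

This vignette explains the models the package implements, the
assumptions behind them, the tunable parameters, and the design choices
made where the methodology was genuinely open. The package addresses one
scientific setting: plate-based single-cell RNA-seq of index-sorted
cells drawn from a one-dimensional, non-branching differentiation
continuum, with ERCC spike-ins and a fluorescent reporter whose level
rises with maturation.

## Data model and normalization

Expression enters as a cell-by-gene matrix of TPM-like relative
abundances. After cell QC (paired reads and expressed genes at or above
their thresholds; *less than* excludes, so equality passes) spike-in
columns are removed and each cell is rescaled so its endogenous values
sum to $10^6$. A TPM value is then interpretable as the within-cell
concentration of a transcript. "Expressed" always means strictly greater
than the cutoff (default 1 TPM); the same strict reading is used by the
gene prevalence filter (> 1 TPM in at least 3 cells) and the ohnolog
binarization, so boundary behavior is consistent across stages.

Because spike-ins are added in a fixed amount per well, the ratio of
endogenous to spike-in signal is proportional to a cell's mRNA content.
The package exposes this as `mrna_content_proxy()`. The proxy's exact
formula is a package convention — relative-abundance data admit no
absolute content estimate — and it is computed before spike-in
stripping, the only point where the information exists.

The default QC thresholds (50,000 reads, 1,000 expressed genes) suit
transcriptome-scale matrices; for the synthetic data, with a few hundred
genes, the expressed-gene threshold must be set proportionally (the
examples use 100). The gene filter runs after renormalization; the one
exception is ohnolog classification, which uses the unfiltered
(renormalized) matrix, because pairs expressed in almost no cells form
the NotExpressed class rather than noise to discard.

## ICA-composite pseudotime

The ordering model assumes gradual transcriptional change along a single
path. ICA is run on log(TPM+1) values, genes standardized, rows sorted
by cell identifier (so results cannot depend on input row order).
Standardization before ICA is a package choice: it makes the ICA input
comparable with the GPLVM's high-variance-gene selection and stops a few
high-amplitude genes from dominating the whitening step.

The component count K defaults to 4 and can be chosen by
`choose_k()`, which operationalizes the qualitative "diminishing
returns" idea: it computes the Frobenius reconstruction error of the
best rank-k approximation and returns the largest k whose marginal error
reduction still exceeds a configurable fraction (default 0.1) of the
k = 1 to 2 reduction.

FastICA (logcosh contrast, symmetric decorrelation, SVD whitening) is
implemented in the package; the initialization is a seeded random
rotation, so a fixed seed gives bitwise-identical factors.
Factors are sign-flipped so each correlates non-negatively with the
recorded reporter fluorescence, then assigned roles:

* **outlier** — the factor with the largest excess kurtosis; a handful
  of aberrant cells (in the emulated design, large high-granularity
  cells, plausibly macrophages carrying reporter signal) load extreme
  values on one factor;
* **difference** — among the rest, the factor with the strongest
  absolute rank correlation with fluorescence (the low-to-high switch);
* **within_small** — of the remaining two, the one with more variance
  among below-median-fluorescence cells;
* **within_large** — the last one.

Ward clustering (`stats::hclust`, `ward.D2`) in factor space yields six
clusters. The cluster most loaded on the outlier factor (ties resolved
toward the smaller cluster) is set aside; the rest are ordered by median
fluorescence (then median difference-factor position, then size, then
index — a fully deterministic tie-break chain) and named 1a, 1b, 2, 3, 4.

The composite pseudotime sorts cells by stage and, within each stage, by
the latent factor that explains that stage's variability. Which factor
that is, is decided per stage as the non-outlier factor with the
strongest within-stage rank correlation to fluorescence, locally
sign-aligned to the fluorescence trend; remaining ties fall through to
fluorescence and then the cell identifier. An earlier design fixed the
stage-to-factor map a priori (within_small for the early stages,
difference across the switch, within_large for the mature stage), but
with four global factors the pre-assigned factor is frequently not the
one carrying local signal in a given stage, and ordering quality inside
the largest stages suffered; selecting the locally informative factor —
which is also what "the factor explaining that cluster's variability"
means operationally — proved markedly more robust and is the package
default. Outlier cells are excluded from the ranking and reported
separately.

`embed_2d()` (exact t-SNE, perplexity default 75, fixed seed) and
`regress_path()` (Nadaraya–Watson smoothing of the embedding against
pseudotime rank) exist for depiction only; no downstream computation
uses them.

## The 1-D GPLVM cross-check

The independent ordering treats each gene as a draw from a zero-mean GP
over an unobserved one-dimensional latent coordinate with a shared RBF
kernel plus noise. The package fits a MAP GPLVM: latent coordinates and
kernel hyperparameters are optimized jointly on the exact log marginal
likelihood plus a standard-normal prior on the latents, with analytic
gradients and L-BFGS. A variational sparse formulation would add
inducing-point machinery without changing the acceptance surface — the
agreement between orderings — so the exact MAP fit is used at this scale
(`n_inducing` is accepted for interface compatibility and ignored).

Genes are reduced to the `n_top_genes` (default 500) most variable
log-transformed columns. The latent is initialized from the first
principal coordinate; `restarts` (default 3) perturbed restarts guard
against local optima and the best objective is kept (the reported
objective never decreases across restarts). The latent's orientation is
arbitrary; `align_orientation()` flips it against any reference, and
`compare_orderings()` reports |Spearman| so orientation never matters.

## Marker discovery

For each cluster a one-vs-rest `ranger` ensemble (impurity importance,
default 1,000 trees) ranks genes by Gini importance, normalized to sum
to one. A thousand trees keep the top of the list stable at interactive
runtimes; ensembles orders of magnitude larger sharpen only the deep
tail of the ranking. Trees are scale-insensitive, so the log transform
of the inputs is cosmetic. `expression_fraction()` reports, per cluster,
the fraction of cells with a gene above the expression cutoff.

## Dynamic genes over pseudotime

Per gene, two GPs are compared on log(TPM+1) against pseudotime rank:
an RBF-kernel GP, which can model change, and a constant-kernel GP,
which cannot. Both subtract the gene's sample mean first, which makes
their log likelihood ratio invariant to affine rescaling of the data.
The constant model's maximum likelihood has a closed form (the kernel's
rank-one-plus-isotropic eigenstructure), including the boundary case
where the constant variance is zero; the RBF model profiles out its
overall scale analytically and optimizes length-scale and
noise-to-signal ratio by Nelder–Mead from several starts. A small noise
floor (1e-6) guards degenerate constant input.

A gene is flagged dynamic when the log likelihood ratio exceeds a
threshold. The threshold is a configuration value; its default (8) was
chosen by null calibration: on white-noise genes the RBF model's extra
flexibility earns a few nats (null ratios have median ~4 and 99th
percentile ~7 at n of 100–300), so the default sits beyond the null's
99th percentile while planted trends score in the hundreds.

Flagged genes' posterior-mean curves, evaluated on a fixed grid and
z-scored, are clustered hierarchically (Ward) into three groups and
relabeled by shape: interior peak (group I), monotone decline (group
II), rise-then-plateau (group III). This curve-clustering stands in for
a full mixture of hierarchical GPs: it has the same acceptance surface
(trend-group recovery) at a fraction of the implementation risk.

## Two-group comparison

`compare_groups()` tests, per gene, a shared Gaussian mean on log(TPM+1)
against separate group means (shared variance) by a likelihood-ratio
test. The reported statistic is $n\log(\mathrm{RSS}_0/\mathrm{RSS}_1)$;
the p-value uses the exact finite-sample F(1, n−2) mapping of that
statistic rather than its asymptotic chi-squared distribution, which is
anti-conservative at group sizes of a few dozen. The Gaussian form is a
convention; zero-inflated genes make log expression bimodal, and the
familywise error of the Holm–Šidák-corrected procedure on such data
runs slightly above its nominal 5% (measured ~5–8% on twin splits of
synthetic mature cells). Consequently, over many replications of a null
comparison a correctly calibrated procedure still produces a
significant gene in roughly one replicate in twenty — zero significant
genes is the typical, not the guaranteed, outcome.

Holm–Šidák itself sorts the raw p-values, adjusts the i-th smallest to
$1-(1-p_{(i)})^{m-i+1}$ (computed via `expm1`/`log1p` so tiny p-values
do not underflow), enforces a running maximum and caps at one.

## Ohnolog pair classification

Expression is binarized at TPM > 1 (strict). For each pair the cells
are partitioned into only-A, only-B, both, and neither, and a fixed
decision tree assigns one of four classes in order: NotExpressed when
more than `not_expressed` cells express neither member; XOR when
`both_min_diff` = min(only-A, only-B) − both exceeds `xor`; Single when
the two members' expressing-cell counts (co-expressing cells included in
both) differ by more than `single`; Mixed otherwise. The default
thresholds (300, 15, 60) are stated for a 363-cell dataset;
`scale_ohnolog_thresholds()` rescales them proportionally for other
sizes. Two readings of the NotExpressed sentence are defensible; the
default counts cells expressing neither member, and the per-gene reading
(each member individually rare) is available behind
`not_expressed_rule = "per_gene"`.

## The synthetic-data generator

`generate_dataset()` emulates the statistical structure the analysis
assumes, with ground truth recorded for every cell, gene and pair. Its
defaults are the package's study conditions and were fixed once:

* ~290 cells (288 on-trajectory plus 1% outliers), 500 endogenous genes,
  20 spike-ins — a two-to-three-plate experiment at desk scale;
* true pseudotime drawn from a five-component truncated-normal mixture
  (centers 0.10–0.85, s.d. 0.045): a continuum with density gaps, which
  is what makes discrete "states" recoverable by clustering at all;
* fluorescence = exponential trend times a sigmoidal jump (the low/high
  gate) with 0.2 log-normal noise;
* gene programs on a log2 scale with amplitudes 5–7: ten monotone
  markers (exponents 0.5–2.5, the first tagged cd41-like), and three
  40-gene trend groups whose transition windows are staggered across
  pseudotime (declines starting 0–0.45, bumps peaking 0.25–0.60, rises
  starting 0.45–0.85) so that every segment of the continuum has active
  transcriptional change — as a real maturation series does; without
  staggering, stages develop internally silent "dead zones" no ordering
  method could resolve;
* log-normal noise (s.d. 0.28 log2 units) and dropout with probability
  0.18 + 0.30·t per cell, attenuated by mean expression as 20/(20+mu) —
  highly expressed transcripts rarely drop out;
* per-cell mRNA content decaying as exp(−2t) against a fixed spike-in
  amount, so the spike-in fraction of the library rises from ~26% to
  ~72% and both the endogenous total and the expressed-gene count fall
  along the continuum;
* ohnolog pairs planted directly as on/off patterns with generous
  margins relative to the (rescaled) thresholds, so classifier recovery
  is exact by construction;
* outlier cells: off-trajectory, FSC/SSC distributions dominating all
  states, and a 30-gene private program.

What the generator does **not** emulate: UMI or read-count noise
(values are TPM-scale from the start), batch and plate effects, doublets,
cell-cycle structure, branching fates, and realistic gene identifiers.
Passing tests therefore demonstrate correctness of the algorithms on
clean, assumption-satisfying data — not robustness to the full mess of
real experiments.

## Numerical choices and degenerate inputs

Zero-variance factors are left unoriented with a warning; zero-variance
input to Spearman correlation is an explicit error (the coefficient is
undefined); a cell with zero endogenous signal aborts rescaling with the
cell named; all-excluded QC is an explicit error; FastICA reports
non-convergence rather than returning a half-converged rotation; GPLVM
restarts that diverge are dropped and the run fails only if all do.
Every stochastic step takes an explicit seed, and the pipeline's
determinism (identical report on identical input and config, regardless
of row order) is part of the test suite.

Problem sizes used by the test and acceptance runs — ~290-cell default
datasets, 110-cell unit fixtures, GP fits over at most a few hundred
genes, 20-replicate null studies — were chosen as the smallest scales at
which the statistical properties under test are stable.

## Known limitations

The trajectory model is strictly one-dimensional: no branch detection is
attempted. The MAP GPLVM provides point estimates, not a posterior over
orderings. The trend-group step classifies only flagged genes and its
shape labels are heuristics over posterior-mean curves. The two-group
test inherits the miscalibration noted above on strongly zero-inflated
genes. The ohnolog decision tree is threshold-based by design; its
counts respond to threshold rescaling, and classes near a boundary are
not distinguished from confident ones.
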