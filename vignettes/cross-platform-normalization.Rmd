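---
title: "Methods: scaling normalization, per-gene ANOVA, and cross-platform concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scaling normalization, per-gene ANOVA, and cross-platform concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normconcord)
```

## The problem

When a laboratory moves its transcriptome profiling from a custom microarray
to RNA-seq, two questions arise at once: which between-sample normalization
should be applied to the read counts, and do the two platforms agree on
which genes are differentially expressed? `normconcord` addresses both for a
bacterial factorial experiment: *Clostridium thermocellum* grown on two
pretreated lignocellulosic substrates (*Populus* and switchgrass) and
sampled at two times during active growth (12 h and 37 h post-inoculation),
with two biological replicate fermentations per condition. RNA-seq yields
one count library per biological sample; the array design adds three
technical replicates per biological sample.

Because the real deposited data are large and external, every stage is
exercised on a synthetic paired-platform generator with known ground truth.
The generator is part of the package, not a test fixture: its defaults *are*
the study conditions, and all calibration claims below refer to them.

## Scaling normalizations

All five RNA-seq methods are scaling methods: each produces one positive
factor $s_j$ per sample, and the normalized value is
$\log_2(x_{gj}/s_j + \text{pseudocount on zeros})$.

* **RPM** — $s_j \propto N_j$, the column total: value
  $x_{gj}\cdot 10^6/N_j$.
* **RPKM** — RPM further divided by gene length in kb:
  $x_{gj}\cdot 10^9/(N_j L_g)$. Genes with no annotated length are dropped
  with a logged count; silently defaulting a length would bias the
  per-kilobase term.
* **UQS** — $s_j$ is the 75th percentile of sample $j$'s *nonzero* counts,
  divided by the geometric mean of those percentiles, so post-normalization
  upper quartiles coincide.
* **TMM** — against a reference sample $r$ (by default, the sample whose
  nonzero upper quartile is closest to the mean of upper quartiles), the
  per-gene log-ratios $M_g=\log_2\frac{x_{gj}/N_j}{x_{gr}/N_r}$ and average
  abundances $A_g$ are computed on genes positive in both samples; the top
  and bottom 30% of $M$ and 5% of $A$ are discarded and the factor is $2$ to
  the precision-weighted mean of the surviving $M$ (weights: inverse
  asymptotic binomial variances). The stored factor is the composition
  factor; the depth-inclusive size factor $N_j f_j$ (geometric mean 1) is
  what `size_factors()` returns and what the normalized matrix uses.
* **KDMM** — against a geometric-mean pseudo-reference over genes positive
  in every sample, a Gaussian-kernel density is fitted to each sample's $M$
  values and the factor is $2$ to the *mode* of that density. The density
  mean of a symmetric-kernel KDE is identical to the arithmetic mean of
  $M$, which would make the kernel fit vacuous, so the mode is the default
  and the mean is selectable (`statistic = "mean"`). The kernel is
  Gaussian with Silverman's rule-of-thumb bandwidth; the original tool's
  kernel and bandwidth are not documented, so these defaults are ours, not
  a claim about that implementation.

Array intensities are normalized by one round of LOESS: per sample, the
deviation from the per-gene all-sample mean intensity is regressed on that
mean (span 0.3 by default, `limma::loessFit`) and the fitted
intensity-dependent curve subtracted. "Single round" rules out iterated
pairwise schemes, which is why the reference is the per-gene mean rather
than cyclic pairs.

### Numerical conventions

* Percentiles use linear interpolation between order statistics (R
  `quantile` type 7). The rule matters only for small samples; it is frozen
  so that factor values are bit-reproducible.
* Ties at percentile or trimming boundaries break by stable input gene
  order.
* Genes with zero counts in **every** sample are removed before any
  analysis. Remaining zero cells receive +1 (configurable) on the
  normalized linear scale before the log2 transform; alternatively
  `zero_policy = "missing"` marks them missing, and downstream correlation
  and ANOVA exclude them pairwise/per gene.
* UQS/TMM/KDMM factors are anchored at geometric mean 1. A consequence
  worth knowing: multiplying one sample's counts by $c$ shifts *every*
  normalized value by the same $\log_2(c)/n$ constant and changes nothing
  else (exactly for UQS and KDMM; approximately for TMM, whose precision
  weights depend weakly on absolute counts).
* The KDMM mode is located by a 2048-point grid argmax refined by local
  optimization of the exact kernel sum; tests verify agreement with an
  exhaustive $10^{-4}$ grid search.

## Per-gene ANOVA and calling rules

Technical array replicates are first collapsed by the arithmetic mean
within each biological sample. Each gene is then fitted with a cell-means
model on the four (substrate, time) groups and a pooled residual variance;
each of the four study contrasts — early vs late on each substrate, and
substrate vs substrate at each time — is a two-sided t-test on the
difference of group means with $n-4$ residual df. This collapse-then-fix
effects scheme approximates the mixed-model, Kenward–Roger analysis used
with nested technical replicates: for balanced designs the group-mean
estimates coincide and the df differences are small. No empirical-Bayes
variance moderation is applied, deliberately: the decision rule being
studied is plain per-gene ANOVA.

P-values are Benjamini–Hochberg adjusted **per contrast across genes**;
per-contrast adjustment is what supports contrast-specific significance
reporting. A gene is *significant* when FDR $<\alpha$ (default 0.05) in at
least one contrast, and *called* when, in at least one contrast, it is
simultaneously significant and beyond the fold threshold
$|\log_2\text{ratio}| \ge \tau$ (default 1). Requiring both flags in the
same contrast is the strictest coherent reading of a fold filter that
subsets the significant list. The log2 ratio is reported left minus right,
so "(*Populus* 12 h) − (switchgrass 12 h)" is positive when the gene is
higher on *Populus*.

Degenerate cases: a condition with fewer than two biological replicates is
a hard error (no residual df); a gene with zero pooled variance gets
$p = 1$ and a warning flag rather than an undefined statistic.

## The synthetic paired-platform generator

Counts for gene $g$ in sample $j$ are negative binomial with mean
$s_j\,\mu_g\,2^{\beta_{g,\mathrm{cond}(j)}}$ and dispersion $\alpha$
($\mathrm{Var}=\mu+\alpha\mu^2$, $\alpha = 0.05$). Gene baselines $\mu_g$
are lognormal (SD 2.0 on the log2 scale) rescaled so the expected library
size is 2 million reads; library-size factors are geometrically spaced with
max/min = 2 — the roughly two-fold spread of uniquely mapped totals the
design emulates — and randomly assigned to samples. Ten percent of genes
carry condition effects built from substrate, time, and interaction
components, each active with probability 1/2, magnitudes uniform on [1, 4]
log2 units, signs balanced by default.

Array intensities share $\mu_g$ and $\beta$ with the counts and add (i) a
gene-specific probe-affinity offset (SD 1.0 log2) constant across samples,
and (ii) independent per-measurement noise (SD 0.35 log2) for each of three
technical replicates. The affinity offset cancels in contrasts — so
cross-platform *fold-change* agreement is high — while degrading absolute
cross-platform correlation into the realistic 0.8–0.9 Spearman band. A
Monte-Carlo sweep over 50 seeds during development placed the per-condition
gene-wise Spearman correlation at roughly 0.86–0.90 under the defaults,
inside the 0.75–0.95 band the tests assert.

One global seed expands into fixed per-stream sub-seeds (gene means,
lengths, effects, size factors, counts, affinity, array noise), so adding
samples extends streams without perturbing earlier draws, and identical
seeds give bitwise-identical matrices.

What the generator does **not** emulate: GC/length-dependent sequencing
bias, transcript-level structure, batch effects, outlier arrays, and
gene–gene correlation. Passing tests therefore demonstrate correctness of
the estimators under the stated stochastic model, not robustness to every
artifact of real libraries.

## Calibration results the tests compute

* KDMM, UQS, and TMM recover the true size factors with median relative
  error ≤ 5% (typically 0.5–3%) at 3,424 genes over 20 seeds.
* RPM is noticeably worse even with sign-balanced effects: with lognormal
  baselines a handful of highly expressed genes dominate each column
  total, so library size is a composition-sensitive depth estimate
  (median relative errors of 9–28% across seeds). Under 20% all-up
  differential expression its systematic bias clearly exceeds KDMM's —
  the directional property the tests assert.
* On 200 null simulations the mean fraction of genes passing FDR < 0.05 in
  any contrast is far below 0.05 (BH under the full null rarely rejects at
  all); with ~200 planted genes at ≥ 2 log2 per component and five
  biological replicates, recall exceeds 80% (typically ≈ 100%) with
  empirical FDR ≤ 0.10.
* Distribution summaries flag RPM and RPKM as shifting normalized medians
  markedly (their factors carry the full 10^6-scale depth rescaling),
  while UQS/KDMM/TMM leave distributions close to the raw log2 counts.

## Concordance analytics

Replicate agreement is Pearson correlation of log2 values between
biological replicates within a condition; cross-platform agreement is
Spearman rank correlation (average ranks on ties) between
replicate-averaged condition profiles restricted to shared genes. Overlap
analysis counts genes — not gene × contrast pairs — called by each
method/platform, because the headline unit of cross-platform agreement is a
gene count; pairwise and three-way Venn regions are reported. Rank
percentiles are ascending average ranks divided by the gene count × 100, so
the most highly expressed gene scores exactly 100. Two-way clustering
row-standardizes each platform/method block (per gene: mean 0, SD 1; a
block-specific transform is needed because platforms differ in scale),
concatenates blocks, and applies Ward (`ward.D2`) hierarchical clustering
on Euclidean distances, cut to exactly *k* clusters (default 10); rows are
pre-sorted by gene id so the partition cannot depend on input order. The
original analysis suite's exact distance/linkage/standardization are
undocumented; these defaults are ours.

## Fermentation and coverage arithmetic

The packaged table `table1_fermentation.tsv` holds the published mean ± SD
fermentation measurements (acetic acid, ethanol, residual glucose) at 0,
12, and 37 h for both substrates. Glucose conversion is
$100\,(g_0 - g_{t})/g_0$ from means; product ratios divide means at a
common time. One documented discrepancy is surfaced deliberately: the
within-substrate acetic:ethanol ratios computed from the table's rounded
means (2.67 and 2.5) cannot reproduce the published 2.20 and 2.05, which
derive from unrounded instrument data; the function attaches a provenance
note instead of silently disagreeing. Platform coverage is a plain
percentage reported at one decimal and at integer rounding
(round-half-to-even).

## Problem sizes and determinism

The shipped tests and the acceptance script run the generator at its
default 3,424-gene scale: 20 seeds for size-factor recovery, 200 null
replicates for FDR calibration, five seeds for the method-agreement and
band checks — sizes chosen so each suite gives stable Monte-Carlo verdicts
while remaining quick on a laptop. `run_pipeline()` writes a manifest
recording the seed, a path-free config hash, per-file MD5 checksums, and
the tuning decisions actually used (pseudocount, percentile rule, KDMM
statistic and bandwidth, TMM trims, LOESS span); identical configurations
and seeds reproduce identical checksums.

## Known limitations

* The KDMM location statistic and kernel settings are an explicit
  interpretation of a tersely described method; both "mode" and "mean"
  readings are implemented, and conclusions that depend on the choice
  should be checked under both.
* The fixed-effects approximation ignores the technical-replicate variance
  component's effect on degrees of freedom; with three technical replicates
  and balanced designs this is small but not zero.
* Missing-value handling is pairwise exclusion, not model-based estimation.
* LOESS normalization assumes most genes are unchanged between samples; a
  globally shifted sample violates the assumption only in its
  intensity-dependent component.
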