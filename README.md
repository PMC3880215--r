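# normconcord

Cross-platform transcriptome normalization and concordance analysis for a
bacterial 2 × 2 factorial design.

## The problem

*Clostridium thermocellum* digests pretreated lignocellulosic biomass
directly, which makes its transcriptional response to different substrates
(*Populus* vs switchgrass, sampled at 12 h and 37 h of fermentation) a key
question for consolidated bioprocessing. Profiling the same cDNA on both a
custom microarray and RNA-seq raises two coupled methods questions that
this package answers with executable code:

1. **Which between-sample normalization for the counts?** Five scaling
   methods are implemented and compared: reads per million (RPM), reads per
   kilobase per million (RPKM), upper-quartile scaling (UQS), trimmed mean
   of M values (TMM), and a kernel-density mode of M values (KDMM) that
   locates the peak of a Gaussian-kernel density fitted to each sample's
   per-gene log2 ratios against a geometric-mean pseudo-reference:

   $$ M_{gj} = \log_2\!\frac{x_{gj}}{(\prod_j x_{gj})^{1/n}}, \qquad
      s_j = 2^{\operatorname{mode}\,\widehat{f}_h(M_{\cdot j})} $$

   Arrays get one round of LOESS normalization (deviation from the
   per-gene mean intensity, regressed on that mean and subtracted).

2. **Do the platforms agree?** Per-gene cell-means ANOVA over the four
   (substrate, time) groups with Benjamini–Hochberg FDR per contrast and a
   fold filter (FDR < 0.05 and |log2 ratio| ≥ 1 in the same contrast),
   followed by concordance analytics: replicate Pearson and cross-platform
   Spearman correlations, gene-level overlap (Venn) counts across
   normalization strategies, expression rank percentiles, and two-way
   Ward clustering.

A paired-platform simulator with known ground truth (negative-binomial
counts plus intensity replicates sharing the same effects, with
probe-affinity offsets and ~2-fold library-size spread) makes every stage
testable without external downloads, including size-factor recovery, FDR
calibration, and recall on planted effects. Desk-scale arithmetic from the
study — glucose conversion bands, fermentation product ratios, platform
gene-coverage percentages — ships as executable summaries with a packaged
data table.

## Worked example

```r
library(normconcord)

sim  <- simulate_experiment(sim_config(seed = 1))   # counts + arrays + truth
norm <- normalize_kdmm(sim$counts)
norm
#> <norm_result> method KDMM; 8 samples, 3424 genes
#>   factors: 0.9027 0.8484 0.799 0.705 1.375 1.043 1.332 1.213

de <- fit_anova(norm, alpha = 0.05, lfc = 1)
summary(de)
#>                             contrast sig sig_fold
#> 1         populus_12h_vs_populus_37h 160      152
#> 2     populus_12h_vs_switchgrass_12h 122      120
#> 3     populus_37h_vs_switchgrass_37h  82       77
#> 4 switchgrass_12h_vs_switchgrass_37h  79       75

cross_platform_correlation(norm$normalized, sim$intensities)
#>         condition spearman_rho n_genes
#> 1     populus_12h    0.8946996    3424
#> 2     populus_37h    0.8855642    3424
#> 3 switchgrass_12h    0.8846191    3424
#> 4 switchgrass_37h    0.8789749    3424

tab <- read_fermentation_table()
glucose_conversion(tab, "populus")          # 62.3% of glucose consumed by 37 h
product_ratio(tab, 37, "populus", "combined")  # 1.57-fold more product on Populus
```

The `factors` line shows the per-sample scaling factors (geometric mean 1)
recovered from the simulated ~2-fold library-size spread; `sig` counts
genes under FDR 0.05 per contrast and `sig_fold` those also beyond 1 log2
unit; the Spearman block shows the realistic 0.88–0.89 cross-platform rank
agreement per condition. An end-to-end run — simulate, six normalizations,
six ANOVA passes, concordance report, manifest with checksums — is
`run_pipeline(run_config(seed = 1))`.

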