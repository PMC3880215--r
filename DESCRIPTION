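Package: normconcord
Title: Cross-Platform Transcriptome Normalization and Concordance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares RNA-seq scaling normalizations (reads per million,
    reads per kilobase per million, upper-quartile scaling, trimmed mean of
    M values, and a kernel-density mode of M values) with LOESS-normalized
    microarray intensities for a bacterial 2 substrate x 2 time-point
    factorial design. Provides per-gene cell-means ANOVA with
    Benjamini-Hochberg false discovery rate control and fold-change calling
    over four condition contrasts, concordance analytics (replicate Pearson
    and cross-platform Spearman correlations, overlap counts, rank
    percentiles, two-way hierarchical clustering), a paired-platform
    negative-binomial count and intensity simulator with ground truth, and
    desk-scale fermentation and gene-coverage arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    limma
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    rtracklayer,
    BiocGenerics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
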