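Package: bsaqtl
Title: Bulked-Segregant QTL-Seq Analysis with Simulation-Based Null Confidence Intervals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for QTL-seq bulked-segregant analysis of biparental
    crosses: per-SNP SNP-index and delta(SNP-index) statistics, 1 Mb / 1 kb
    sliding-window averaging, Monte-Carlo confidence intervals for
    delta(SNP-index) under the null hypothesis of no QTL, candidate-region
    calling and gene-interval arithmetic, a regression-based F2 linkage
    confirmation scan (LOD, R-squared, additive and dominance effects), and
    phenotype statistics (CV, broad-sense heritability, joint ANOVA).
    Includes a synthetic F2-cross and bulk-sequencing generator so every
    stage is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
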