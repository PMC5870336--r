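# bsaqtl

QTL-seq bulked-segregant analysis for biparental crosses, packaged as a
reusable, fully testable pipeline. The motivating use case is mapping a
major plant-height QTL in soybean from two sequenced DNA pools of
phenotypic extremes of an F2 population, followed by marker-based linkage
confirmation — but every stage works on any two-bulk design.

The pipeline covers:

* **SNP-index statistics** — per-SNP `SNP-index = alt/(ref+alt)` per bulk
  and `Δ(SNP-index) = index(high bulk) − index(low bulk)`, averaged in
  sliding windows (1 Mb window, 1 kb step by default);
* **Monte-Carlo null confidence intervals** — Δ simulated under no QTL by
  double binomial sampling (n individuals into each bulk, then reads over
  the pool), tabulated by read depth; windows whose mean Δ escape the band
  are flagged;
* **Candidate-region calling** — flagged windows merged into regions, with
  interval arithmetic (widths in bp/kb/Mb, half-up rounded) and gene
  overlap against GFF3/TSV annotations;
* **Linkage confirmation** — a regression QTL scan on the F2 genotypes
  (LOD, R², additive and dominance effects; single-marker and
  Haley–Knott-style interval versions; permutation thresholds);
* **Phenotype statistics** — descriptives (mean ± SD, range, CV),
  broad-sense heritability from replicated family ANOVA, joint
  genotype × environment ANOVA;
* **A synthetic generator** — F2 meiosis under the Haldane map function,
  a one-QTL trait model `y = μ + a·x + d·z + ε`, rank-selected bulks and
  Poisson/binomial pooled read sampling, so the whole pipeline is testable
  with known ground truth (and writes standard VCF/CSV interchange files).

Statistical details and design rationale are in
`vignettes/qtlseq-methods.Rmd`.

## Worked example

`analysis/` holds numbered drivers that run the whole study on a simulated
cross: a 349-plant F2 segregating one QTL (a = 3, d = 0.5, σₑ = 3) at
35 Mb of a 45 Mb chromosome, bulks of 20, ~10× pooled coverage. Running

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_qtlseq.R
Rscript analysis/03_null_ci.R
Rscript analysis/04_region_call.R
Rscript analysis/05_linkage_scan.R
Rscript analysis/06_pheno_stats.R
```

prints, among other things:

```
simulated 349 F2 plants, 900 markers on chr13 (45 Mb)
bulk phenotype ranges: high 56.5-61.0, low 36.8-43.6
filter report: input 900, kept 889, removed_qual 0, removed_depth 11
windows: 45000 (0 empty); mean delta within 0.5 Mb of the QTL: 0.71
95% band at depth 10: [-0.50, 0.50]; at depth 40: [-0.30, 0.32]
planted QTL at 35.00 Mb covered: TRUE
published region width: 1.73 Mb; marker span: 69.3 kb; genes contained: 12
scan peak: chr13_034950000 (34.95 Mb) LOD 35.67, R2 37.5%, a = 3.50, d = 0.28 (truth a = 3, d = 0.5)
genome-wide LOD threshold (alpha 0.05, 1000 permutations): 2.10
broad-sense h2 in ENV1: 60.59% (r = 3, 349 families)
```

Reading the output: the windowed Δ(SNP-index) near the planted QTL (~0.7)
far exceeds the 95% null band at 10× depth (±0.5), the called candidate
region covers the true QTL position, and the marker scan confirms it with
LOD ≈ 36 well above the 1,000-permutation genome-wide threshold, with an
additive-effect estimate near the planted value. The interval arithmetic
lines reproduce the published physical distances of the soybean
plant-height QTL region (1.73 Mb candidate region; 69.3 kb flanking-marker
span containing 12 annotated genes) from the marker and gene coordinate
tables shipped under `inst/extdata/`.

Equivalent results come from the single entry point:

```r
library(bsaqtl)
report <- run_pipeline(pipeline_config(seed = 1))
print(report)
plot_indices(report$windows, report$regions)
```

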