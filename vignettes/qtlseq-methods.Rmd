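---
title: "QTL-seq bulked-segregant analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QTL-seq bulked-segregant analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsaqtl)
```

## The method

Bulked-segregant analysis by whole-genome sequencing (QTL-seq) locates a
quantitative trait locus by sequencing two pooled DNA samples drawn from the
phenotypic extremes of a segregating population — here an F2 of a biparental
soybean cross, with 20 tall and 20 short plants per bulk. At every SNP the
**SNP-index** of a bulk is the fraction of reads carrying the allele that
differs from the reference genome,

$$\mathrm{SNP\text{-}index} = \frac{n_\mathrm{alt}}{n_\mathrm{ref} + n_\mathrm{alt}},$$

so 0 means all reads match the recurrent (reference) parent, 1 means all
reads carry the donor allele, and 0.5 an equal genomic contribution.
**Δ(SNP-index)** is the difference between the high- and low-bulk indices.
Away from any trait locus both bulks are random draws of the population and
Δ fluctuates around 0; at a locus where the donor allele raises the trait,
the high bulk is enriched and the low bulk depleted for it, pushing Δ
towards +1.

Per-SNP indices are noisy at ~10× coverage, so the genome is scanned with a
sliding window (1 Mb window, 1 kb increment by default) and the unweighted
mean index of the SNPs in each window is plotted. Windows are anchored at
position 1 with a fixed step so the window set is reproducible and
independent of SNP density; empty windows are reported as empty and never
interpolated.

### Sign convention

We fix Δ = high-bulk index − low-bulk index. With the donor allele
increasing the trait, the candidate region is where the high bulk's index
approaches 1 and the low bulk's approaches 0, i.e. Δ is significantly
*positive*. Region calling therefore uses the positive side by default;
two-sided and negative-side flagging are available for traits where the
donor allele acts in the other direction.

## The null model for Δ(SNP-index)

Significance is judged against Monte-Carlo confidence intervals computed
under the null hypothesis of no QTL. Each replicate mimics the two sampling
stages of the design, independently per bulk:

1. *individuals into the bulk*: the bulk allele count is
   $K \sim \mathrm{Binomial}(2n, \tfrac12)$ over the $2n$ gametes of the
   $n$ bulked F2 plants, giving a bulk allele frequency $p = K/2n$;
2. *reads over the pooled DNA*: the alt read count is
   $A \sim \mathrm{Binomial}(D, p)$ at read depth $D$.

Δ is the difference of the two simulated read fractions. For each depth on
a grid the 2.5% and 97.5% empirical quantiles of 10,000 replicates (by
default) form the 95% band; a window is flagged when its mean Δ escapes the
band looked up at the window's rounded mean depth (nearest tabulated depth
at or below, clamped to the grid — no interpolation, which keeps the bound
monotone in depth up to Monte-Carlo noise).

### Discreteness at low depth

At equal bulk depths $D$ the null Δ is supported on the lattice
$\{-1, \dots, 1\}$ in steps of $1/D$. At the study's 10× depth the
attainable two-sided coverages of a symmetric band jump from 93.3%
(band ±0.4) to 97.7% (band ±0.5): *no* band covers exactly 95%. The
inclusive empirical quantile band (±0.5) is therefore conservative — its
true coverage is ~97.7%, and the per-window false-flag rate is
correspondingly below the nominal 5%. The test suite checks nominal
coverage at a depth where the lattice is fine (depth 97) and
conservativeness at depth 10. Users comparing flag counts against a nominal
5% at low depth should expect fewer.

Note also that the band is tabulated for the *per-SNP* sampling
distribution while it is compared against *window means*, whose
read-sampling noise is averaged over the SNPs in the window. This follows
the original QTL-seq procedure and is a second source of conservatism;
the bulk-composition component of the noise is shared by the SNPs of a
window and is not reduced by averaging.

## The synthetic cross

The generator reproduces the study design end to end so that every stage
has ground-truth inputs:

* **Meiosis.** Each F2 individual receives two haplotypes from independent
  meioses; recombination between adjacent loci follows the Haldane map
  function $r = (1 - e^{-2m/100})/2$ on their cM distance (no crossover
  interference — the standard choice for QTL-seq simulators; the data give
  no basis for an interference model). Single-marker genotypes segregate
  1:2:1 as expected in an F2.
* **Trait model.** One QTL with phenotype
  $y = \mu + a x + d z + \varepsilon$, $x \in \{-1, 0, +1\}$ for
  {AA, AB, BB} (B = donor allele), $z = \mathbf 1[\mathrm{AB}]$,
  $\varepsilon \sim N(0, \sigma_e^2)$. Defaults $\mu = 50$ cm, $a = 3$,
  $d = 0.5$, $\sigma_e = 3$ place the simulated trait in the range of the
  parental plant heights and give a single major QTL of realistic effect.
* **Bulking.** Pure rank selection: the 20 largest and 20 smallest
  phenotypes, ties broken by individual index so runs are deterministic.
* **Read sampling.** Per marker and bulk, depth is zero-truncated
  Poisson(10) and the alt count Binomial(depth, bulk allele frequency) —
  approximately 10× coverage with no sequencing-error model.
* **Coordinates.** One 45 Mb chromosome (the size of the QTL-bearing
  soybean chromosome) with one SNP per 50 kb and a constant 2.5 cM/Mb —
  the genome-wide average recombination rate; the QTL sits at 35 Mb.
* **Family phenotyping.** Heritability and ANOVA work on replicated family
  means; the generator phenotypes each F2 plant through five selfed
  progeny, mirroring family-based evaluation.

One integer seed fans out into named substreams (meiosis, phenotype noise,
read sampling per bulk, null simulation), so any stage can be regenerated
without replaying the others and full runs are byte-reproducible.

### What the generator does not emulate

Real data differ in ways that matter for interpretation. SNPs are not
evenly spaced; in a cross against a chromosome-segment substitution line
they exist *only inside donor segments*, which sharply truncates the
Δ profile at segment boundaries and is one reason published candidate
regions can be much narrower than a freely segregating simulation
suggests. Recombination is far from uniform — distal euchromatin
recombines at several times the genome average while pericentromeric
regions barely recombine — and sequencing carries base errors and mapping
biases that the read model omits. Passing recovery tests on this generator
therefore demonstrates correctness of the statistics and of the pipeline's
plumbing, not field performance on any particular genome.

A consequence worth stating explicitly: under a constant genome-average
recombination rate the true Δ profile around the QTL is a broad plateau
(the expected allele-frequency displacement decays only by $(1-2r)$), so
the location of the windowed maximum wanders by 1–3 Mb between replicates.
The called *region* essentially always covers the QTL, but the *peak
window* lands within 2 Mb of it in only roughly 80–90% of replicates at
these settings. With locally realistic (higher) recombination rates the
plateau narrows and localisation tightens; we keep the genome-average
default rather than tuning the simulator to its own test.

## Candidate regions and interval arithmetic

Flagged windows are merged into maximal runs (a configurable number of
unflagged windows, default 0, may be bridged). Because consecutive windows
overlap by `window − step`, runs separated in index can still overlap in
coordinates; regions are reported per run, as the window bookkeeping
defines them. Two width conventions coexist deliberately:

* a *region's* `width` is `end − start + 1` (1-based inclusive span);
* `interval_width()` reports `end − start`, the physical-distance
  convention used for marker-to-marker spans (left marker's start to right
  marker's end) and for Mb-rounded region bounds, with half-up rounding.
  This convention reproduces the published 69.3 kb marker span and 1.73 Mb
  region width exactly; the alternative inner-span convention does not.

Gene overlap supports both `any_overlap` and `contained` modes plus a
configurable flank, because published gene counts for a region sometimes
include genes straddling or just outside the stated bounds; we expose the
choice instead of guessing a rule. On-disk regions are BED (0-based
half-open, converted and tested); annotations are GFF3 gene features or a
plain TSV.

## The confirmation scan

The linkage-confirmation step is a transparent least-squares QTL scan, a
deliberate stand-in for proprietary composite-interval-mapping software
(whose algorithm is both unavailable and peripheral here). At each marker:

$$y = \mu + a x + d z + \varepsilon$$

fitted by OLS on individuals with non-missing genotypes (casewise
deletion; with ~350 plants imputation buys little). From the residual sums
of squares of this and the intercept-only model,

$$\mathrm{LOD} = \frac{n}{2}\log_{10}\frac{RSS_0}{RSS_1}, \qquad
R^2 = 100\,(1 - RSS_1/RSS_0),$$

and $a$, $d$ are the fitted coefficients ($a > 0$: donor allele increases
the trait). Both statistics are invariant to affine rescaling of the
phenotype. If a genotype class is absent the reduced model is fitted and
flagged. Between markers, `scan_interval()` replaces $x$ and $z$ by their
conditional expectations given the flanking marker genotypes under Haldane
recombination (the two gametes are independent Markov chains, so
$P(Q \mid L, R) \propto T_{r_1}[L,Q]\,T_{r_2}[Q,R]$ with the F2 genotype
transition matrix $T_r$) — a Haley–Knott-style regression on expected
dosages. Genome-wide significance uses a 1,000-permutation threshold on
the maximum LOD at α = 0.05, since no threshold is prescribed for the
confirmation scan.

## Phenotype statistics

`describe()` reports mean, sample SD ($n-1$), range and CV = 100·SD/mean.
Broad-sense heritability uses the one-way random-effects ANOVA estimator
on replicated family values:

$$\sigma_g^2 = \frac{MS_\mathrm{family} - MS_\mathrm{error}}{r}, \qquad
h^2 = 100\,\frac{\sigma_g^2}{\sigma_g^2 + MS_\mathrm{error}},$$

with $r$ the replicate count (harmonic mean when unbalanced) and negative
$\sigma_g^2$ truncated to zero. $MS_\mathrm{error}$ estimates the
within-family variance, so $h^2$ targets the plot-basis ratio
$\sigma_g^2/(\sigma_g^2+\sigma_e^2)$; this is the standard estimator for
replicated family trials and is stated in all reports since published
tables rarely print their formula. `joint_anova()` is the ordinary two-way
fixed-effects ANOVA with interaction; its sums of squares partition the
total exactly, which the tests assert as an identity.

## Numerical and testing choices

* Quantiles everywhere are R's default inclusive order-statistic
  interpolation (type 7).
* Zero-depth SNPs are removed by the depth filter (default per-bulk bounds
  [4, 200]; the quality cutoff is 20), never imputed; `snp_index()` refuses
  zero total depth rather than guessing.
* Filters apply in a fixed order (quality, then depth) and removals are
  attributed to the first failing rule, so report counts partition the
  input — an invariant the tests check.
* Windowed means use cumulative sums over position-sorted SNPs
  (O(windows + SNPs)); a brute-force per-window scan serves as the oracle
  in tests.
* Test and calibration problem sizes are chosen so the full suite runs in
  about a minute on one core: recovery loops use 50 replicates of the
  349-plant design; coverage checks use 10⁵ null replicates; the
  simulated chromosome is 45 Mb with 900 markers. These sizes give
  Monte-Carlo error comfortably inside every asserted tolerance.

## Known limitations

Single-QTL trait model (no epistasis, no multi-QTL scans); biallelic SNPs
only (indels and multiallelic sites are skipped and counted); no
sequencing-error or mapping-bias model; the null CI is per-SNP and hence
conservative for window means at low depth; heritability is the entry-mean
ANOVA estimator, not REML; and the simulator segregates the whole
chromosome freely, which is pessimistic for peak localisation relative to
a substitution-line cross (see above).
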