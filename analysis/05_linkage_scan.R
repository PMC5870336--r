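#!/usr/bin/env Rscript
# Confirm the candidate region in the F2 population with the regression
# scan: single-marker LOD / R2 / additive / dominance statistics over the
# markers near the called region, an interval scan between them, and a
# 1000-permutation genome-wide LOD threshold.

suppressPackageStartupMessages(library(bsaqtl))

cfg <- pipeline_config(seed = 1)
geno <- read.csv("results/genotypes.csv", check.names = FALSE)
phe <- read.csv("results/phenotypes.csv")
regions <- read.delim("results/regions.tsv")
truth <- jsonlite::read_json("results/truth.json")

map <- genetic_map(setNames(cfg$chrom_length, cfg$chrom_name),
                   spacing = cfg$marker_spacing, cm_per_mb = cfg$cm_per_mb)
centre <- if (nrow(regions)) {
  regions$peak_pos[which.max(abs(regions$peak_delta))]
} else truth$pos
keep <- map$markers[abs(map$markers$pos - centre) <= 5e6, ]
g <- as.matrix(geno[, keep$marker])
ds <- f2_dataset(g, phe$phenotype, keep)

sc <- scan_markers(ds)
write.table(sc, "results/scan_markers.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
peak <- sc[which.max(sc$lod), ]
cat(sprintf("scan peak: %s (%.2f Mb) LOD %.2f, R2 %.1f%%, a = %.2f, d = %.2f (truth a = %g, d = %g)\n",
            peak$marker, peak$pos / 1e6, peak$lod, peak$r2, peak$a, peak$d,
            truth$a, truth$d))

thr <- perm_threshold(ds, n_perm = 1000, alpha = 0.05,
                      seed = substream_seed(cfg$seed, "perm"))
cat(sprintf("genome-wide LOD threshold (alpha 0.05, 1000 permutations): %.2f\n",
            thr$threshold))
cat(sprintf("markers above threshold: %d of %d\n",
            sum(sc$lod > thr$threshold), nrow(sc)))
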