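#!/usr/bin/env Rscript
# Simulate the bulked-segregant experiment: a 349-plant F2 from a biparental
# cross segregating one plant-height QTL (a = 3, d = 0.5, env_sd = 3) on a
# 45 Mb chromosome, extreme bulks of 20 plants, and ~10x pooled reads per
# SNP per bulk. Writes the two-bulk VCF, genotype/phenotype tables and the
# simulation truth used by the later steps.

suppressPackageStartupMessages(library(bsaqtl))
dir.create("results", showWarnings = FALSE)

cfg <- pipeline_config(seed = 1)
map <- genetic_map(setNames(cfg$chrom_length, cfg$chrom_name),
                   spacing = cfg$marker_spacing, cm_per_mb = cfg$cm_per_mb)
qtl <- qtl_model(cfg$chrom_name, cfg$qtl_pos, a = cfg$a, d = cfg$d,
                 env_sd = cfg$env_sd, mu = cfg$mu)
sim <- simulate_qtlseq(map, qtl, n = cfg$n_ind, n_high = cfg$bulk_size,
                       n_low = cfg$bulk_size, depth_mean = cfg$depth_mean,
                       seed = cfg$seed)

write_bulk_vcf(sim$records, "results/bulks.vcf")
write.csv(data.frame(id = seq_along(sim$pop$phenotype),
                     phenotype = sim$pop$phenotype),
          "results/phenotypes.csv", row.names = FALSE)
write.csv(cbind(id = seq_len(nrow(sim$pop$geno)), as.data.frame(sim$pop$geno)),
          "results/genotypes.csv", row.names = FALSE)
jsonlite::write_json(sim$truth, "results/truth.json", auto_unbox = TRUE)

cat(sprintf("simulated %d F2 plants, %d markers on %s (%.0f Mb)\n",
            cfg$n_ind, nrow(sim$records), cfg$chrom_name,
            cfg$chrom_length / 1e6))
cat(sprintf("bulk phenotype ranges: high %.1f-%.1f, low %.1f-%.1f\n",
            min(sim$pop$phenotype[sim$bulks$high_ids]),
            max(sim$pop$phenotype[sim$bulks$high_ids]),
            min(sim$pop$phenotype[sim$bulks$low_ids]),
            max(sim$pop$phenotype[sim$bulks$low_ids])))
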