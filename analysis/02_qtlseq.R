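#!/usr/bin/env Rscript
# QTL-seq statistics on the simulated bulks: read the two-bulk VCF, apply
# the quality (>= 20) and depth filters, compute per-SNP SNP-index and
# delta(SNP-index), and average them in 1 Mb sliding windows at 1 kb steps.

suppressPackageStartupMessages(library(bsaqtl))

cfg <- pipeline_config(seed = 1)
rec <- read_bulk_variants("results/bulks.vcf")
flt <- apply_filters(rec, filter_policy(cfg$min_qual, cfg$min_depth,
                                        cfg$max_depth))
cat("filter report:", paste(names(flt$report), flt$report, collapse = ", "),
    "\n")

idx <- snp_index_table(flt$kept)
win <- sliding_windows(idx, setNames(cfg$chrom_length, cfg$chrom_name),
                       window = cfg$window, step = cfg$step)

write.table(idx, "results/snp_index.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(win, "results/windows.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

near <- subset(win, !empty & abs((win_start + win_end) / 2 - cfg$qtl_pos) < 5e5)
cat(sprintf("windows: %d (%d empty); mean delta within 0.5 Mb of the QTL: %.2f\n",
            nrow(win), sum(win$empty), mean(near$mean_delta)))
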