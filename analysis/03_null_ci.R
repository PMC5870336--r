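#!/usr/bin/env Rscript
# Monte-Carlo null confidence intervals for delta(SNP-index): for each read
# depth, simulate bulk allele frequencies (Binomial(2n, 1/2) over n = 20
# individuals) and read sampling, and tabulate the 95% band. Flag windows
# whose mean delta escapes the band on the positive side.

suppressPackageStartupMessages(library(bsaqtl))

cfg <- pipeline_config(seed = 1)
tab <- build_ci_table(n = cfg$bulk_size, depth_grid = cfg$ci_depth_grid,
                      level = cfg$level, reps = cfg$ci_reps,
                      seed = substream_seed(cfg$seed, "ci"))
write.table(tab, "results/null_ci.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("95%% band at depth 10: [%.2f, %.2f]; at depth 40: [%.2f, %.2f]\n",
            tab$lower[tab$depth == 10], tab$upper[tab$depth == 10],
            tab$lower[tab$depth == 40], tab$upper[tab$depth == 40]))

win <- read.delim("results/windows.tsv")
win <- flag_windows(win, tab, side = cfg$side)
write.table(win, "results/windows_flagged.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("flagged windows: %d of %d non-empty\n", sum(win$flagged),
            sum(!win$empty)))
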