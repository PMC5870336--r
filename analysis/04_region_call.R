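#!/usr/bin/env Rscript
# Merge significant windows into candidate regions, report their widths,
# check whether the planted QTL is covered, and plot the SNP-index tracks.
# Also reproduces the interval arithmetic on the published coordinates:
# candidate-region width, flanking-marker span, and genes contained.

suppressPackageStartupMessages(library(bsaqtl))

win <- read.delim("results/windows_flagged.tsv")
truth <- jsonlite::read_json("results/truth.json")
regions <- call_regions(win, max_gap = 0)
write.table(regions, "results/regions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_regions_bed(regions, "results/regions.bed")

cat(sprintf("%d candidate region(s)\n", nrow(regions)))
covered <- any(regions$start <= truth$pos & regions$end >= truth$pos)
cat(sprintf("planted QTL at %.2f Mb covered: %s\n", truth$pos / 1e6, covered))

plot_indices(win, regions, out = "results/snp_index_plot.png")

# published-coordinate arithmetic (soybean chromosome 13 plant-height QTL)
markers <- read.delim(system.file("extdata", "ssr_markers_qph13.tsv",
                                  package = "bsaqtl"))
genes <- read_gene_annotation(system.file("extdata", "genes_qph13.tsv",
                                          package = "bsaqtl"))
flank <- markers[markers$marker %in% c("BARCSOYSSR_13_1417",
                                       "BARCSOYSSR_13_1421"), ]
qregion <- list(chrom = "Gm13", start = 34.20e6, end = 35.93e6)
cat(sprintf("published region width: %.2f Mb; marker span: %.1f kb; genes contained: %d\n",
            interval_width(qregion$start, qregion$end, "Mb", 2),
            interval_width(min(flank$start), max(flank$end), "kb", 1),
            length(overlap_genes(qregion, genes, "contained"))))
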