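test_that("no flagged windows yields no regions", {
  win <- window_fixture(rep(FALSE, 10))
  expect_equal(nrow(call_regions(win)), 0)
})

test_that("a contiguous flagged run reproduces the 1 Mb-window span width", {
  # run of 1 Mb windows starting 34,200,001 ... 34,930,001 at 1 kb step
  starts <- seq(34200001, 34930001, by = 1000)
  before <- seq(34150001, 34200000, by = 1000)
  win <- data.frame(chrom = "chr13",
                    win_start = c(before, starts),
                    win_end = c(before, starts) + 1e6 - 1,
                    n_snps = 5L, mean_hph = 0.9, mean_lph = 0.1,
                    mean_delta = 0.8, mean_depth = 10, empty = FALSE,
                    flagged = c(rep(FALSE, length(before)),
                                rep(TRUE, length(starts))))
  reg <- call_regions(win)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start, 34200001)
  expect_equal(reg$end, 35930000)
  expect_equal(reg$width, 1730000)
  expect_equal(reg$n_windows, length(starts))
})

test_that("max_gap bridges short unflagged gaps", {
  win <- window_fixture(c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(nrow(call_regions(win, max_gap = 0)), 2)
  merged <- call_regions(win, max_gap = 1)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$n_windows, 4)   # flagged windows only
  expect_equal(merged$start, win$win_start[1])
  expect_equal(merged$end, win$win_end[5])
})

test_that("region calling matches a brute-force scan on random fixtures", {
  for (s in 1:10) {
    set.seed(s)
    win <- window_fixture(runif(200) < 0.2)
    for (gap in 0:2) {
      reg <- call_regions(win, max_gap = gap)
      oracle <- brute_regions(win, max_gap = gap)
      if (is.null(oracle)) {
        expect_equal(nrow(reg), 0)
      } else {
        expect_equal(reg$start, oracle$start, ignore_attr = TRUE)
        expect_equal(reg$end, oracle$end, ignore_attr = TRUE)
      }
    }
  }
})

test_that("regions from non-overlapping windows are disjoint at max_gap 0", {
  set.seed(99)
  win <- window_fixture(runif(300) < 0.3)
  reg <- call_regions(win, max_gap = 0)
  if (nrow(reg) > 1) {
    expect_true(all(reg$start[-1] > reg$end[-nrow(reg)]))
  }
  expect_lte(sum(reg$width), max(win$win_end))
})

test_that("the peak is the strongest window, leftmost on ties", {
  win <- window_fixture(c(TRUE, TRUE, TRUE))
  win$mean_delta <- c(0.5, 0.9, 0.9)
  reg <- call_regions(win)
  expect_equal(reg$peak_delta, 0.9)
  expect_equal(reg$peak_pos, (win$win_start[2] + win$win_end[2]) / 2)
})

test_that("interval widths reproduce the printed physical distances", {
  # QTL-seq candidate region bounds in Mb
  expect_equal(interval_width(34.20e6, 35.93e6, "Mb", 2), 1.73)
  # flanking-marker span: left marker start to right marker end
  expect_equal(interval_width(35668210, 35737464, "kb", 1), 69.3)
  expect_equal(interval_width(100, 100, "bp"), 0)
  expect_error(interval_width(200, 100), "negative")
})

test_that("half-up rounding is used for reported widths", {
  expect_equal(interval_width(0, 1350, "kb", 2), 1.35)
  expect_equal(interval_width(0, 125, "bp", -1), 130)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-2.5), -3)
})

test_that("gene overlap modes behave as set operations on the annotation", {
  genes <- read_gene_annotation(
    system.file("extdata", "genes_qph13.tsv", package = "bsaqtl"))
  marker_iv <- list(chrom = "Gm13", start = 35668210, end = 35737464)
  hits_any <- overlap_genes(marker_iv, genes, "any_overlap")
  hits_in <- overlap_genes(marker_iv, genes, "contained")
  expect_true("Glyma.13g249400" %in% hits_in)
  # the left-neighbour gene ends before the marker interval begins
  expect_false("Glyma.13g248600" %in% hits_any)
  expect_true(all(hits_in %in% hits_any))
  # sorted by start
  expect_equal(hits_any, hits_any[order(match(hits_any, genes$id))])
  expect_equal(overlap_genes(marker_iv, genes[0, ]), character())
  expect_warning(
    overlap_genes(list(chrom = "chr99", start = 1, end = 2), genes),
    "chr99")
})

test_that("BED export converts 1-based inclusive to 0-based half-open", {
  reg <- data.frame(chrom = "chr13", start = 34200001, end = 35930000,
                    width = 1730000, n_windows = 1L, peak_delta = 0.8,
                    peak_pos = 35e6)
  path <- withr::local_tempfile(fileext = ".bed")
  write_regions_bed(reg, path)
  bed <- read.delim(path, header = FALSE)
  expect_equal(bed$V2, 34200000)
  expect_equal(bed$V3, 35930000)
  expect_equal(bed$V3 - bed$V2, reg$width)
})

test_that("GFF3 gene features are parsed into annotated intervals", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t100\t200\t.\t+\t.\tID=geneA;Name=a",
               "chr1\tsrc\tmRNA\t100\t200\t.\t+\t.\tID=geneA.1",
               "chr1\tsrc\tgene\t300\t400\t.\t-\t.\tID=geneB"), path)
  g <- read_gene_annotation(path)
  expect_equal(g$id, c("geneA", "geneB"))
  expect_equal(g$start, c(100, 300))
})
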