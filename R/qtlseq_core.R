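#' SNP-index: fraction of reads carrying the non-reference allele
#'
#' The SNP-index at a site is the proportion of reads harbouring the allele
#' that differs from the reference sequence. With the recurrent parent as
#' the reference, an index of 0 means all reads match the recurrent parent,
#' 1 means all reads carry the donor allele, and 0.5 an equal genome
#' contribution from both parents.
#'
#' @param ref_count,alt_count read counts (vectors of equal length).
#' @return numeric index in \[0, 1\].
#' @export
snp_index <- function(ref_count, alt_count) {
  total <- ref_count + alt_count
  if (any(total <= 0)) {
    stop("zero total depth at ", sum(total <= 0),
         " site(s); apply a depth filter first")
  }
  alt_count / total
}

#' Difference of SNP-indices between the high and low bulks
#'
#' delta = high-bulk index minus low-bulk index, oriented so a donor allele
#' that increases the trait gives positive delta (high bulk enriched for the
#' donor allele: index near 1 in the high bulk, near 0 in the low bulk).
#'
#' @param hph_index,lph_index SNP-indices in \[0, 1\].
#' @return delta in \[-1, 1\].
#' @export
delta_snp_index <- function(hph_index, lph_index) {
  if (any(hph_index < 0 | hph_index > 1 | lph_index < 0 | lph_index > 1)) {
    stop("SNP-indices must lie in [0, 1]")
  }
  hph_index - lph_index
}

#' Per-SNP index table for a filtered record stream
#'
#' @param records a filtered `bulk_variants` data.frame (positive depth in
#'   both bulks at every site).
#' @return data.frame chrom, pos, hph_index, lph_index, delta, hph_depth,
#'   lph_depth.
#' @export
snp_index_table <- function(records) {
  hph_depth <- records$hph_ref + records$hph_alt
  lph_depth <- records$lph_ref + records$lph_alt
  hi <- snp_index(records$hph_ref, records$hph_alt)
  li <- snp_index(records$lph_ref, records$lph_alt)
  data.frame(chrom = records$chrom, pos = records$pos,
             hph_index = hi, lph_index = li,
             delta = delta_snp_index(hi, li),
             hph_depth = hph_depth, lph_depth = lph_depth,
             stringsAsFactors = FALSE)
}

## windowed mean of v over sorted positions via cumulative sums:
## O(windows + snps) instead of one scan per window
window_means <- function(pos, v, starts, ends) {
  cs <- c(0, cumsum(v))
  hi <- findInterval(ends, pos)
  lo <- findInterval(starts - 1, pos) + 1L
  n <- pmax(hi - lo + 1L, 0L)
  s <- cs[hi + 1L] - cs[lo]
  list(n = n, mean = ifelse(n > 0, s / pmax(n, 1L), NA_real_))
}

#' Sliding-window averages of SNP-index and delta(SNP-index)
#'
#' Average SNP-index of the SNPs in each genomic interval, computed with a
#' sliding window (default 1 Mb window, 1 kb increment). Windows are
#' anchored at position 1 with a fixed step, independent of SNP density;
#' a window covers \[start, min(start + window - 1, chrom_len)\] (1-based
#' inclusive). Means are unweighted arithmetic means over the SNPs inside;
#' windows with no SNPs are emitted flagged empty, never interpolated.
#'
#' @param indices per-SNP table from [snp_index_table()], sorted by
#'   (chrom, pos).
#' @param chrom_len named vector of chromosome lengths in bp (names may be
#'   omitted when `indices` has a single chromosome).
#' @param window window size in bp (default 1e6).
#' @param step window increment in bp (default 1e3); `window >= step >= 1`.
#' @return data.frame chrom, win_start, win_end, n_snps, mean_hph, mean_lph,
#'   mean_delta, mean_depth, empty (logical).
#' @export
sliding_windows <- function(indices, chrom_len, window = 1e6, step = 1e3) {
  stopifnot(window >= step, step >= 1)
  chroms <- unique(indices$chrom)
  if (is.null(names(chrom_len))) {
    if (length(chrom_len) == 1 && length(chroms) <= 1) {
      names(chrom_len) <- if (length(chroms)) chroms else "chr1"
    } else stop("chrom_len must be named for multi-chromosome input")
  }
  out <- lapply(names(chrom_len), function(ch) {
    d <- indices[indices$chrom == ch, , drop = FALSE]
    if (nrow(d) > 1 && is.unsorted(d$pos)) {
      i <- which(diff(d$pos) < 0)[1]
      stop("unsorted positions on ", ch, ": pos ", d$pos[i + 1],
           " after ", d$pos[i])
    }
    starts <- seq(1, chrom_len[[ch]], by = step)
    ends <- pmin(starts + window - 1, chrom_len[[ch]])
    depth <- (d$hph_depth + d$lph_depth) / 2
    mh <- window_means(d$pos, d$hph_index, starts, ends)
    ml <- window_means(d$pos, d$lph_index, starts, ends)
    md <- window_means(d$pos, d$delta, starts, ends)
    mdep <- window_means(d$pos, depth, starts, ends)
    data.frame(chrom = ch, win_start = starts, win_end = ends,
               n_snps = mh$n, mean_hph = mh$mean, mean_lph = ml$mean,
               mean_delta = md$mean, mean_depth = mdep$mean,
               empty = mh$n == 0, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
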