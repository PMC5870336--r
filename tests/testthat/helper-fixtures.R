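# shared fixture builders and brute-force oracles

# minimal f2_population with fixed genotypes (bypasses meiosis)
fixed_population <- function(geno, phenotype = rep(0, nrow(geno)),
                             chrom = "chr1", spacing = 5e4) {
  m <- ncol(geno)
  pos <- seq(spacing, by = spacing, length.out = m)
  colnames(geno) <- sprintf("%s_%09d", chrom, pos)
  map <- structure(list(
    chromosomes = data.frame(chrom = chrom, length = pos[m] + spacing),
    markers = data.frame(marker = colnames(geno), chrom = chrom,
                         pos = pos, cm = pos / 1e6 * 2.5)
  ), class = "genetic_map")
  structure(list(geno = geno, qtl_geno = rep("AB", nrow(geno)),
                 phenotype = phenotype, map = map,
                 qtl = qtl_model(chrom, pos[1], a = 0), seed = 0),
            class = "f2_population")
}

# random bulk_variants table
random_records <- function(n, seed = 1, chrom = "chr1", max_pos = 1e6) {
  set.seed(seed)
  pos <- sort(sample.int(max_pos, n))
  dh <- rpois(n, 12) + 1
  dl <- rpois(n, 12) + 1
  ah <- rbinom(n, dh, 0.5)
  al <- rbinom(n, dl, 0.5)
  data.frame(chrom = chrom, pos = pos, ref_allele = "A", alt_allele = "T",
             hph_ref = dh - ah, hph_alt = ah,
             lph_ref = dl - al, lph_alt = al,
             qual = round(runif(n, 10, 60), 1), stringsAsFactors = FALSE)
}

# brute-force windowed means: one explicit scan per window
brute_windows <- function(indices, chrom_len, window, step) {
  starts <- seq(1, chrom_len, by = step)
  do.call(rbind, lapply(starts, function(s) {
    e <- min(s + window - 1, chrom_len)
    inw <- indices$pos >= s & indices$pos <= e
    data.frame(win_start = s, win_end = e, n_snps = sum(inw),
               mean_delta = if (any(inw)) mean(indices$delta[inw]) else NA)
  }))
}

# brute-force region merge over flagged windows (max_gap unflagged allowed)
brute_regions <- function(windows, max_gap = 0) {
  idx <- which(windows$flagged)
  if (length(idx) == 0) return(NULL)
  groups <- cumsum(c(TRUE, diff(idx) > max_gap + 1))
  do.call(rbind, lapply(split(idx, groups), function(members) {
    data.frame(start = windows$win_start[members[1]],
               end = windows$win_end[members[length(members)]])
  }))
}

# non-overlapping flagged-window fixture on a unit grid
window_fixture <- function(flags, width = 100) {
  n <- length(flags)
  starts <- seq(1, by = width, length.out = n)
  data.frame(chrom = "chr1", win_start = starts,
             win_end = starts + width - 1, n_snps = 1L,
             mean_hph = 0.5, mean_lph = 0.5,
             mean_delta = ifelse(flags, 0.9, 0), mean_depth = 10,
             empty = FALSE, flagged = flags)
}
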