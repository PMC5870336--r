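#' Read two-bulk variant records from a VCF or TSV file
#'
#' Builds the per-SNP record table the pipeline operates on: one row per
#' biallelic SNP with ref/alt read counts in each bulk, taken from the
#' per-sample AD (allele depth) field. Multiallelic sites and non-SNP
#' variants (indels) are skipped and counted. A plain TSV dialect with
#' columns chrom, pos, ref_allele, alt_allele, hph_ref, hph_alt, lph_ref,
#' lph_alt, qual is accepted as an alternative input.
#'
#' @param path path to an uncompressed VCF 4.x (with per-sample AD) or to
#'   the TSV dialect.
#' @param hph_sample,lph_sample sample names of the high- and low-phenotype
#'   bulks (VCF only).
#' @return a `bulk_variants` data.frame (chrom, pos, ref_allele, alt_allele,
#'   hph_ref, hph_alt, lph_ref, lph_alt, qual), ordered as in the file, with
#'   attribute `skipped` = count of multiallelic/non-SNP lines dropped.
#' @export
read_bulk_variants <- function(path, hph_sample = "HPH", lph_sample = "LPH") {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "##fileformat=VCF")) {
    return(read_bulk_tsv(path))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)   # single-variant files drop dims
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)[-1]
  for (s in c(hph_sample, lph_sample)) {
    if (!s %in% samples) {
      stop("sample '", s, "' not in VCF; available: ",
           paste(samples, collapse = ", "))
    }
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(dim(ad))) ad <- matrix(ad, nrow = 1, dimnames = list(NULL, samples))
  is_snp <- !grepl(",", fix$ALT, fixed = TRUE) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L & fix$ALT != "."
  skipped <- sum(!is_snp)

  parse_ad <- function(x) {
    parts <- strsplit(ifelse(is.na(x), "0,0", x), ",", fixed = TRUE)
    t(vapply(parts, function(p) as.numeric(p[1:2]), numeric(2)))
  }
  h <- parse_ad(ad[, hph_sample])
  l <- parse_ad(ad[, lph_sample])
  out <- data.frame(
    chrom = fix$CHROM, pos = as.numeric(fix$POS),
    ref_allele = fix$REF, alt_allele = fix$ALT,
    hph_ref = h[, 1], hph_alt = h[, 2],
    lph_ref = l[, 1], lph_alt = l[, 2],
    qual = as.numeric(fix$QUAL), stringsAsFactors = FALSE
  )[is_snp, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, skipped = skipped, class = c("bulk_variants", "data.frame"))
}

read_bulk_tsv <- function(path) {
  need <- c("chrom", "pos", "ref_allele", "alt_allele",
            "hph_ref", "hph_alt", "lph_ref", "lph_alt", "qual")
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character",
                                        ref_allele = "character",
                                        alt_allele = "character"))
  if (nrow(d) == 0 && ncol(d) == 1) {   # headerless empty file
    d <- stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(need))),
                         need)
  }
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop("TSV is missing columns: ", paste(missing, collapse = ", "))
  }
  num <- c("pos", "hph_ref", "hph_alt", "lph_ref", "lph_alt", "qual")
  for (col in num) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]))
    if (length(bad)) {
      stop("malformed TSV line ", bad[1] + 1L, " (column ", col, ") in ", path)
    }
    d[[col]] <- v
  }
  structure(d[need], skipped = 0L,
            class = c("bulk_variants", "data.frame"))
}

#' Write two-bulk variant records
#'
#' Writers for the two on-disk interchange formats: the TSV dialect (exactly
#' the columns [read_bulk_variants()] expects back) and a minimal two-sample
#' VCF 4.2 with per-sample AD, one variant line per marker.
#'
#' @param records a `bulk_variants` data.frame.
#' @param path output path.
#' @param hph_sample,lph_sample sample names written to the VCF header.
#' @return the path, invisibly.
#' @export
write_bulk_tsv <- function(records, path) {
  cols <- c("chrom", "pos", "ref_allele", "alt_allele",
            "hph_ref", "hph_alt", "lph_ref", "lph_alt", "qual")
  utils::write.table(records[cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bulk_tsv
#' @export
write_bulk_vcf <- function(records, path, hph_sample = "HPH",
                           lph_sample = "LPH") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=bsaqtl",
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", hph_sample, lph_sample, sep = "\t")
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t.\tAD\t%d,%d\t%d,%d",
                  records$chrom, as.integer(records$pos),
                  records$ref_allele, records$alt_allele,
                  format(records$qual, trim = TRUE),
                  as.integer(records$hph_ref), as.integer(records$hph_alt),
                  as.integer(records$lph_ref), as.integer(records$lph_alt))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Quality and depth filter policy for bulk variant records
#'
#' Sites with a base quality below 20 are excluded as likely false positives
#' from repeats or sequencing/alignment error; at the post-calling stage the
#' site QUAL field stands in for base quality. Depth bounds guard against
#' uncovered and collapsed-repeat sites; they default to \[4, 200\] per bulk
#' and are configurable.
#'
#' @param min_qual minimum phred site quality (default 20).
#' @param min_depth_per_bulk,max_depth_per_bulk per-bulk total depth
#'   (ref + alt) bounds, applied to both bulks.
#' @param biallelic_only keep only biallelic SNPs (record stream from
#'   [read_bulk_variants()] is already biallelic).
#' @return a `filter_policy` list.
#' @export
filter_policy <- function(min_qual = 20, min_depth_per_bulk = 4,
                          max_depth_per_bulk = 200, biallelic_only = TRUE) {
  stopifnot(min_depth_per_bulk >= 0,
            min_depth_per_bulk <= max_depth_per_bulk)
  structure(list(min_qual = min_qual,
                 min_depth_per_bulk = min_depth_per_bulk,
                 max_depth_per_bulk = max_depth_per_bulk,
                 biallelic_only = biallelic_only),
            class = "filter_policy")
}

#' Apply the quality/depth filter policy to a record stream
#'
#' Rules are applied in a fixed order — site quality first, then per-bulk
#' depth — and each removal is attributed to the first rule that fails, so
#' the report counts partition the removed records.
#'
#' @param records a `bulk_variants` data.frame.
#' @param policy a [filter_policy()].
#' @return list with `kept` (filtered records) and `report` (named counts:
#'   input, kept, removed_qual, removed_depth).
#' @export
apply_filters <- function(records, policy = filter_policy()) {
  n <- nrow(records)
  if (n == 0) {
    return(list(kept = records,
                report = c(input = 0, kept = 0,
                           removed_qual = 0, removed_depth = 0)))
  }
  fail_qual <- records$qual < policy$min_qual
  dh <- records$hph_ref + records$hph_alt
  dl <- records$lph_ref + records$lph_alt
  ok_depth <- dh >= policy$min_depth_per_bulk &
    dh <= policy$max_depth_per_bulk &
    dl >= policy$min_depth_per_bulk &
    dl <= policy$max_depth_per_bulk
  fail_depth <- !fail_qual & !ok_depth
  kept <- records[!fail_qual & ok_depth, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept,
       report = c(input = n, kept = nrow(kept),
                  removed_qual = sum(fail_qual),
                  removed_depth = sum(fail_depth)))
}
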