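#' Merge significant windows into candidate QTL regions
#'
#' Maximal runs of flagged windows on a chromosome are merged into
#' contiguous candidate regions; up to `max_gap` consecutive unflagged (or
#' empty) windows are tolerated inside a run. The region spans from the
#' first window's start to the last window's end; the peak is the flagged
#' window with the largest |mean delta| (leftmost on ties).
#'
#' @param windows flagged window table from [flag_windows()], sorted by
#'   (chrom, win_start).
#' @param max_gap consecutive non-flagged windows allowed inside a region
#'   (default 0: the regions are strictly contiguous runs).
#' @return data.frame of candidate regions: chrom, start, end, width
#'   (end - start + 1), n_windows (flagged windows merged), peak_delta,
#'   peak_pos; zero rows when nothing is flagged.
#' @export
call_regions <- function(windows, max_gap = 0) {
  empty_out <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), width = numeric(),
                          n_windows = integer(), peak_delta = numeric(),
                          peak_pos = numeric(), stringsAsFactors = FALSE)
  regions <- list()
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    if (is.unsorted(w$win_start)) stop("windows unsorted on ", ch)
    idx <- which(w$flagged)
    if (length(idx) == 0) next
    run_break <- c(TRUE, diff(idx) > max_gap + 1L)
    run_id <- cumsum(run_break)
    for (r in unique(run_id)) {
      members <- idx[run_id == r]
      sub <- w[members, , drop = FALSE]
      peak <- which.max(abs(sub$mean_delta))   # leftmost on ties
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = ch,
        start = sub$win_start[1],
        end = sub$win_end[nrow(sub)],
        width = sub$win_end[nrow(sub)] - sub$win_start[1] + 1,
        n_windows = length(members),
        peak_delta = sub$mean_delta[peak],
        peak_pos = (sub$win_start[peak] + sub$win_end[peak]) / 2,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(regions) == 0) return(empty_out)
  out <- do.call(rbind, regions)
  rownames(out) <- NULL
  out
}

#' Width of a genomic interval in bp, kb or Mb
#'
#' Span width measured as end minus start, the convention used for
#' marker-to-marker intervals (left marker's start to right marker's end),
#' converted to the requested unit and rounded half-up.
#'
#' @param start,end interval bounds in bp (end >= start).
#' @param unit "bp", "kb" or "Mb".
#' @param decimals decimal places of the result (default 1).
#' @return rounded width in `unit`.
#' @export
interval_width <- function(start, end, unit = c("bp", "kb", "Mb"),
                           decimals = 1) {
  unit <- match.arg(unit)
  if (any(end < start)) stop("negative interval width")
  div <- c(bp = 1, kb = 1e3, Mb = 1e6)[[unit]]
  round_half_up((end - start) / div, decimals)
}

#' Genes overlapping or contained in a candidate region
#'
#' @param region one-row region (list/data.frame with chrom, start, end).
#' @param genes data.frame of annotated intervals: id, chrom, start, end.
#' @param mode "any_overlap" keeps genes whose span intersects the region;
#'   "contained" requires the gene to lie entirely within it.
#' @param flank symmetric extension of the region in bp before testing
#'   (default 0).
#' @return character vector of gene ids, sorted by start position.
#' @export
overlap_genes <- function(region, genes, mode = c("any_overlap", "contained"),
                          flank = 0) {
  mode <- match.arg(mode)
  if (nrow(genes) == 0) return(character())
  same <- genes$chrom == region$chrom
  if (!any(same)) {
    warning("no genes on chromosome ", region$chrom,
            " (annotation uses: ", paste(unique(genes$chrom), collapse = ", "),
            ")")
    return(character())
  }
  lo <- region$start - flank
  hi <- region$end + flank
  hit <- if (mode == "any_overlap") {
    same & genes$start <= hi & genes$end >= lo
  } else {
    same & genes$start >= lo & genes$end <= hi
  }
  genes$id[hit][order(genes$start[hit])]
}

#' Read gene annotations from GFF3 or a TSV
#'
#' GFF3 files are reduced to their `gene` features (id from the ID= tag);
#' the TSV alternative needs columns id, chrom, start, end.
#'
#' @param path annotation file.
#' @return data.frame id, chrom, start, end.
#' @export
read_gene_annotation <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##gff-version")) {
    g <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
    g <- g[g[[3]] == "gene", , drop = FALSE]
    id <- sub(";.*$", "", sub("^.*ID=", "", g[[9]]))
    return(data.frame(id = id, chrom = g[[1]], start = as.numeric(g[[4]]),
                      end = as.numeric(g[[5]]), stringsAsFactors = FALSE))
  }
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "start", "end")
  if (!all(need %in% names(d))) {
    stop("annotation TSV needs columns: ", paste(need, collapse = ", "))
  }
  d[need]
}

#' Write candidate regions as BED
#'
#' Converts the internal 1-based inclusive coordinates to BED's 0-based
#' half-open convention (start - 1, end).
#'
#' @param regions region table from [call_regions()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = format(regions$start - 1, scientific = FALSE,
                                   trim = TRUE),
                    end = format(regions$end, scientific = FALSE, trim = TRUE))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
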