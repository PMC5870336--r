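#' Default pipeline configuration
#'
#' Stage parameters default to the study design: 1 Mb window, 1 kb step,
#' 95% confidence level, bulks of 20, minimum site quality 20, mean depth
#' 10x, an F2 of 349 plants, and a single 45 Mb chromosome carrying one QTL.
#'
#' @param ... overrides for any configuration key.
#' @return a named list of pipeline parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    chrom_length = 45e6, chrom_name = "chr13",
    marker_spacing = 5e4, cm_per_mb = 2.5,
    n_ind = 349, qtl_pos = 35e6, a = 3, d = 0.5, env_sd = 3, mu = 50,
    bulk_size = 20, depth_mean = 10,
    min_qual = 20, min_depth = 4, max_depth = 200,
    window = 1e6, step = 1e3,
    level = 0.95, ci_reps = 10000, ci_depth_grid = 1:60,
    side = "positive", max_gap = 0,
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  utils::modifyList(cfg, over)
}

#' Run the full QTL-seq pipeline on a simulated cross
#'
#' Executes simulate -> bulk -> read sampling -> filter -> SNP-index ->
#' sliding windows -> null CI -> flag -> region call -> linkage scan ->
#' phenotype statistics as one configured, seeded run. The run is
#' deterministic: identical configuration and seed reproduce the report
#' exactly.
#'
#' @param config list from [pipeline_config()].
#' @return a `run_report` list: config, truth, filter report, windows,
#'   regions, scan (marker scan over markers within 5 Mb of the strongest
#'   region, or the QTL neighbourhood when no region is called), pheno
#'   (descriptives of the population phenotype), and per-stage record
#'   counts.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  map <- genetic_map(stats::setNames(config$chrom_length, config$chrom_name),
                     spacing = config$marker_spacing,
                     cm_per_mb = config$cm_per_mb)
  qtl <- qtl_model(config$chrom_name, config$qtl_pos, a = config$a,
                   d = config$d, env_sd = config$env_sd, mu = config$mu)
  sim <- simulate_qtlseq(map, qtl, n = config$n_ind,
                         n_high = config$bulk_size,
                         n_low = config$bulk_size,
                         depth_mean = config$depth_mean, seed = config$seed)
  flt <- apply_filters(sim$records,
                       filter_policy(config$min_qual, config$min_depth,
                                     config$max_depth))
  idx <- snp_index_table(flt$kept)
  win <- sliding_windows(idx,
                         stats::setNames(config$chrom_length,
                                         config$chrom_name),
                         window = config$window, step = config$step)
  ci <- build_ci_table(n = config$bulk_size,
                       depth_grid = config$ci_depth_grid,
                       level = config$level, reps = config$ci_reps,
                       seed = substream_seed(config$seed, "ci"))
  win <- flag_windows(win, ci, side = config$side)
  regions <- call_regions(win, max_gap = config$max_gap)

  # confirmation scan over markers near the called region (or the QTL)
  centre <- if (nrow(regions)) {
    regions$peak_pos[which.max(abs(regions$peak_delta))]
  } else config$qtl_pos
  near <- map$markers$marker[map$markers$pos >= centre - 5e6 &
                               map$markers$pos <= centre + 5e6]
  scan <- scan_markers(as_f2_dataset(sim$pop, markers = near))

  structure(list(
    config = config, truth = sim$truth, filter_report = flt$report,
    ci_table = ci, windows = win, regions = regions, scan = scan,
    pheno = describe(sim$pop$phenotype),
    counts = c(markers = nrow(sim$records), kept = nrow(flt$kept),
               windows = nrow(win), flagged = sum(win$flagged),
               regions = nrow(regions))
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("QTL-seq pipeline run (seed ", x$config$seed, ")\n", sep = "")
  cat(" markers: ", x$counts[["markers"]], " simulated, ",
      x$counts[["kept"]], " kept after filtering\n", sep = "")
  cat(" windows: ", x$counts[["windows"]], " (",
      x$counts[["flagged"]], " significant at level ",
      x$config$level, ")\n", sep = "")
  if (nrow(x$regions)) {
    cat(" candidate regions:\n")
    for (i in seq_len(nrow(x$regions))) {
      r <- x$regions[i, ]
      cat(sprintf("  %s:%.2f-%.2f Mb (width %.2f Mb, peak delta %.2f)\n",
                  r$chrom, r$start / 1e6, r$end / 1e6, r$width / 1e6,
                  r$peak_delta))
    }
  } else cat(" candidate regions: none\n")
  peak <- x$scan[which.max(x$scan$lod), ]
  cat(sprintf(" scan peak: %s at %.2f Mb, LOD %.2f, R2 %.1f%%, a=%.2f, d=%.2f\n",
              peak$marker, peak$pos / 1e6, peak$lod, peak$r2, peak$a, peak$d))
  invisible(x)
}

#' Manhattan-style plots of windowed SNP-index and delta(SNP-index)
#'
#' Three stacked tracks — high-bulk SNP-index, low-bulk SNP-index, and
#' delta with its null confidence band — with candidate regions shaded.
#' Lines break across empty windows.
#'
#' @param windows flagged window table from [flag_windows()].
#' @param regions region table from [call_regions()] (may have zero rows).
#' @param out optional path; when given the figure is written there (png).
#' @return the ggplot object, invisibly when written to file.
#' @export
plot_indices <- function(windows, regions = NULL, out = NULL) {
  w <- windows[!windows$empty, , drop = FALSE]
  if (nrow(w) == 0) stop("no non-empty windows to plot")
  mb <- (w$win_start + w$win_end) / 2e6
  long <- rbind(
    data.frame(chrom = w$chrom, mb = mb, value = w$mean_hph,
               track = "HPH-pool SNP-index"),
    data.frame(chrom = w$chrom, mb = mb, value = w$mean_lph,
               track = "LPH-pool SNP-index"),
    data.frame(chrom = w$chrom, mb = mb, value = w$mean_delta,
               track = "Delta(SNP-index)")
  )
  long$track <- factor(long$track, levels = unique(long$track))
  band <- data.frame(chrom = w$chrom, mb = mb, lower = w$lower,
                     upper = w$upper, track = levels(long$track)[3])
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$mb, y = .data$value)) +
    ggplot2::geom_ribbon(data = band,
                         ggplot2::aes(x = .data$mb, ymin = .data$lower,
                                      ymax = .data$upper),
                         inherit.aes = FALSE, fill = "steelblue",
                         alpha = 0.3) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(track ~ chrom, scales = "free") +
    ggplot2::labs(x = "Position (Mb)", y = NULL) +
    ggplot2::theme_bw()
  if (!is.null(regions) && nrow(regions)) {
    shade <- data.frame(chrom = regions$chrom, xmin = regions$start / 1e6,
                        xmax = regions$end / 1e6)
    p <- p + ggplot2::geom_rect(data = shade,
                                ggplot2::aes(xmin = .data$xmin,
                                             xmax = .data$xmax),
                                ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
                                fill = "firebrick", alpha = 0.15)
  }
  if (!is.null(out)) {
    ggplot2::ggsave(out, p, width = 9, height = 6, dpi = 150)
    return(invisible(p))
  }
  p
}
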