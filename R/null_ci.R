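#' Simulate delta(SNP-index) under the null hypothesis of no QTL
#'
#' Double-binomial null model: each replicate first samples the bulk's
#' allele frequency — K ~ Binomial(2n, 0.5) alleles among the 2n gametes of
#' the n bulked F2 individuals, p = K / (2n) — independently for each bulk,
#' then samples reads A ~ Binomial(depth, p) per bulk; delta is the
#' difference of the two read fractions. This reproduces both sources of
#' sampling noise in a bulked-segregant design: individuals into the bulk,
#' and reads over the pooled DNA.
#'
#' @param n bulked individuals per bulk (>= 1).
#' @param depth_h,depth_l read depths of the high and low bulk (>= 1).
#' @param reps Monte-Carlo replicates.
#' @param seed integer seed.
#' @return numeric vector of `reps` delta values in \[-1, 1\].
#' @export
simulate_null_delta <- function(n, depth_h, depth_l, reps = 10000, seed = 1) {
  stopifnot(n >= 1, depth_h >= 1, depth_l >= 1, reps >= 1)
  set.seed(substream_seed(seed, "null_delta"))
  p_h <- stats::rbinom(reps, 2 * n, 0.5) / (2 * n)
  p_l <- stats::rbinom(reps, 2 * n, 0.5) / (2 * n)
  stats::rbinom(reps, depth_h, p_h) / depth_h -
    stats::rbinom(reps, depth_l, p_l) / depth_l
}

#' Tabulate null confidence intervals of delta(SNP-index) by read depth
#'
#' For each depth on the grid (used symmetrically for both bulks) the
#' (1-level)/2 and 1-(1-level)/2 empirical quantiles of the simulated null
#' delta distribution give the interval bounds. Lookups use the nearest
#' tabulated depth at or below the query, clamped to the grid ends — no
#' interpolation, which keeps the bound monotone in depth up to Monte-Carlo
#' noise.
#'
#' @param n bulked individuals per bulk (default 20, the study design).
#' @param depth_grid integer vector of read depths to tabulate.
#' @param level confidence level in (0, 1), default 0.95.
#' @param reps Monte-Carlo replicates per depth (default 10000).
#' @param seed integer seed; each depth uses a derived stream.
#' @return a `null_ci_table`: data.frame (depth, lower, upper) with
#'   attributes n, level, reps, seed.
#' @export
build_ci_table <- function(n = 20, depth_grid = 1:60, level = 0.95,
                           reps = 10000, seed = 1) {
  stopifnot(level > 0, level < 1)
  if (length(depth_grid) == 0) stop("depth grid is empty")
  depth_grid <- sort(unique(as.integer(depth_grid)))
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  rows <- t(vapply(depth_grid, function(d) {
    delta <- simulate_null_delta(n, d, d, reps,
                                 substream_seed(seed, paste0("depth", d)))
    stats::quantile(delta, probs, names = FALSE, type = 7)
  }, numeric(2)))
  structure(data.frame(depth = depth_grid,
                       lower = rows[, 1], upper = rows[, 2]),
            n = n, level = level, reps = reps, seed = seed,
            class = c("null_ci_table", "data.frame"))
}

## nearest tabulated depth at or below the query, clamped to the grid ends
lookup_ci <- function(table, depth) {
  i <- findInterval(depth, table$depth)
  i <- pmin(pmax(i, 1L), nrow(table))
  table[i, c("lower", "upper"), drop = FALSE]
}

#' Annotate windows with null CI bounds and significance flags
#'
#' Each non-empty window gets the (lower, upper) null bounds at its rounded
#' mean read depth and a flag for each side of the interval; `flagged` is
#' the side requested. The positive side is the default: with the donor
#' allele increasing the trait, a real QTL drives windowed delta above the
#' upper bound.
#'
#' @param windows data.frame from [sliding_windows()].
#' @param table a `null_ci_table` from [build_ci_table()] built with the
#'   matching bulk size.
#' @param side which exceedances count as significant: "positive"
#'   (delta > upper), "negative" (delta < lower) or "both".
#' @return `windows` with columns lower, upper, flagged added (NA/FALSE for
#'   empty windows).
#' @export
flag_windows <- function(windows, table, side = c("positive", "negative",
                                                  "both")) {
  side <- match.arg(side)
  stopifnot(inherits(table, "null_ci_table"))
  bounds <- lookup_ci(table, round(windows$mean_depth))
  windows$lower <- ifelse(windows$empty, NA_real_, bounds$lower)
  windows$upper <- ifelse(windows$empty, NA_real_, bounds$upper)
  up <- !windows$empty & windows$mean_delta > windows$upper
  dn <- !windows$empty & windows$mean_delta < windows$lower
  windows$flagged <- switch(side,
    positive = up, negative = dn, both = up | dn)
  windows$flagged[is.na(windows$flagged)] <- FALSE
  windows
}
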