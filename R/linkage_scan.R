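#' Assemble an F2 mapping dataset
#'
#' Bundles the marker genotype matrix, the marker map and the phenotype
#' vector (typically family means phenotyping each F2 plant) for the
#' confirmation scan.
#'
#' @param geno individuals x markers character matrix with values
#'   "AA"/"AB"/"BB" or NA (A = recurrent-parent allele, B = donor allele).
#' @param phenotype numeric vector, one value per individual.
#' @param map data.frame marker, chrom, pos (bp), cm — one row per genotyped
#'   marker, in map order.
#' @return an `f2_dataset`.
#' @export
f2_dataset <- function(geno, phenotype, map) {
  stopifnot(nrow(geno) == length(phenotype),
            all(colnames(geno) == map$marker))
  ok <- geno %in% c("AA", "AB", "BB") | is.na(geno)
  if (!all(ok)) stop("genotypes must be AA/AB/BB or NA")
  structure(list(geno = geno, phenotype = phenotype, map = map),
            class = "f2_dataset")
}

#' Extract an F2 mapping dataset from a simulated population
#'
#' @param pop an `f2_population` from [simulate_f2()].
#' @param phenotype phenotype vector to map (defaults to the plants' own
#'   simulated values; pass [family_means()] output to emulate family-based
#'   phenotyping).
#' @param markers optional subset of marker names to genotype.
#' @return an `f2_dataset`.
#' @export
as_f2_dataset <- function(pop, phenotype = pop$phenotype, markers = NULL) {
  map <- pop$map$markers
  if (!is.null(markers)) map <- map[map$marker %in% markers, , drop = FALSE]
  f2_dataset(pop$geno[, map$marker, drop = FALSE], phenotype, map)
}

## core regression at one locus given numeric additive (x) and dominance (z)
## predictors; returns LOD, R2 (%), a, d, n_used
fit_locus <- function(y, x, z) {
  keep <- !is.na(y) & !is.na(x) & !is.na(z)
  y <- y[keep]; x <- x[keep]; z <- z[keep]
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  X <- cbind(1, x, z)
  # drop collapsed predictors (a genotype class absent) to keep the fit valid
  keep_col <- c(TRUE, stats::sd(x) > 0, stats::sd(z) > 0)
  fit <- stats::lm.fit(X[, keep_col, drop = FALSE], y)
  rss1 <- sum(fit$residuals^2)
  coefs <- c(a = NA_real_, d = NA_real_)
  cf <- fit$coefficients[-1]
  names(cf) <- c("a", "d")[keep_col[-1]]
  coefs[names(cf)] <- cf
  lod <- if (rss1 <= 0) Inf else max(0, (n / 2) * log10(rss0 / rss1))
  r2 <- if (rss0 <= 0) 0 else 100 * (1 - rss1 / rss0)
  c(lod = lod, r2 = r2, a = unname(coefs["a"]), d = unname(coefs["d"]),
    n_used = n, reduced = as.numeric(!all(keep_col)))
}

geno_to_x <- function(g) c(AA = -1, AB = 0, BB = 1)[g]
geno_to_z <- function(g) c(AA = 0, AB = 1, BB = 0)[g]

#' Single-marker regression QTL scan
#'
#' At each marker the phenotype is regressed on the additive dose
#' x in \{-1, 0, +1\} for \{AA, AB, BB\} and the dominance indicator
#' z = 1\[AB\] by least squares; individuals with a missing genotype are
#' dropped casewise. LOD = (n/2) log10(RSS0/RSS1) against the intercept-only
#' model and R2 = 100 (1 - RSS1/RSS0). A positive additive effect means the
#' donor (B) allele increases the trait. Markers where a genotype class is
#' absent are fitted with the reduced model and flagged.
#'
#' @param data an [f2_dataset()].
#' @param min_n minimum non-missing individuals per marker (default 10);
#'   markers below it are skipped with a warning.
#' @return a `scan_result` data.frame: marker, chrom, pos, cm, lod, r2, a,
#'   d, n_used, reduced.
#' @export
scan_markers <- function(data, min_n = 10) {
  stopifnot(inherits(data, "f2_dataset"))
  rows <- lapply(seq_len(nrow(data$map)), function(j) {
    g <- data$geno[, j]
    n_ok <- sum(!is.na(g) & !is.na(data$phenotype))
    if (n_ok < min_n) {
      warning("marker ", data$map$marker[j], " skipped: only ", n_ok,
              " genotyped individuals")
      return(NULL)
    }
    if (length(unique(stats::na.omit(g))) < 2) {
      warning("marker ", data$map$marker[j], " is monomorphic; reduced fit")
    }
    stats_j <- fit_locus(data$phenotype, geno_to_x(g), geno_to_z(g))
    cbind(data$map[j, c("marker", "chrom", "pos", "cm")],
          as.data.frame(as.list(stats_j)))
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("scan_result", "data.frame"))
}

## F2 genotype transition matrix over recombination fraction r
## (two independent gamete Markov chains, collapsed to unordered genotypes)
geno_transition <- function(r) {
  matrix(c((1 - r)^2, 2 * r * (1 - r), r^2,
           r * (1 - r), (1 - r)^2 + r^2, r * (1 - r),
           r^2, 2 * r * (1 - r), (1 - r)^2),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("AA", "AB", "BB"), c("AA", "AB", "BB")))
}

## conditional genotype probabilities at a pseudo-locus given the (possibly
## missing) flanking genotypes, Haldane distances in cM
qtl_geno_prob <- function(left_g, right_g, cm_left, cm_right) {
  prior <- c(AA = 0.25, AB = 0.5, BB = 0.25)
  tl <- geno_transition(haldane_r(cm_left))
  tr <- geno_transition(haldane_r(cm_right))
  n <- length(left_g)
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, names(prior)))
  for (i in seq_len(n)) {
    w <- if (is.na(left_g[i])) prior else tl[left_g[i], ]
    if (!is.na(right_g[i])) w <- w * tr[, right_g[i]]
    out[i, ] <- w / sum(w)
  }
  out
}

#' Interval (pseudo-position) regression QTL scan
#'
#' Haley–Knott-style extension of [scan_markers()]: on a cM grid along each
#' chromosome the additive and dominance predictors are replaced by their
#' conditional expectations given the flanking marker genotypes under
#' Haldane recombination, and the same least-squares statistics are
#' computed. At a fully informative marker the expectations collapse to the
#' observed codes and the statistics equal the single-marker scan.
#'
#' @param data an [f2_dataset()].
#' @param step_cm grid spacing in cM (default 1).
#' @return a `scan_result` data.frame with pseudo-positions (marker = NA at
#'   interior grid points).
#' @export
scan_interval <- function(data, step_cm = 1) {
  stopifnot(inherits(data, "f2_dataset"))
  out <- list()
  for (ch in unique(data$map$chrom)) {
    mp <- data$map[data$map$chrom == ch, , drop = FALSE]
    if (nrow(mp) < 2) {
      out[[ch]] <- scan_markers(f2_dataset(
        data$geno[, mp$marker, drop = FALSE], data$phenotype, mp))
      next
    }
    grid <- sort(unique(c(seq(mp$cm[1], mp$cm[nrow(mp)], by = step_cm),
                          mp$cm)))
    bp_per_cm <- (mp$pos[nrow(mp)] - mp$pos[1]) /
      max(mp$cm[nrow(mp)] - mp$cm[1], 1e-9)
    rows <- lapply(grid, function(cm) {
      at_marker <- which(abs(mp$cm - cm) < 1e-9)
      if (length(at_marker)) {
        j <- at_marker[1]
        g <- data$geno[, mp$marker[j]]
        x <- geno_to_x(g); z <- geno_to_z(g)
        marker <- mp$marker[j]; pos <- mp$pos[j]
      } else {
        left <- max(which(mp$cm < cm))
        right <- min(which(mp$cm > cm))
        pr <- qtl_geno_prob(data$geno[, mp$marker[left]],
                            data$geno[, mp$marker[right]],
                            cm - mp$cm[left], mp$cm[right] - cm)
        x <- pr[, "BB"] - pr[, "AA"]
        z <- pr[, "AB"]
        marker <- NA_character_
        pos <- mp$pos[left] + (cm - mp$cm[left]) * bp_per_cm
      }
      stats_j <- fit_locus(data$phenotype, x, z)
      data.frame(marker = marker, chrom = ch, pos = pos, cm = cm,
                 as.data.frame(as.list(stats_j)), stringsAsFactors = FALSE)
    })
    out[[ch]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("scan_result", "data.frame"))
}

#' Genome-wide permutation LOD threshold
#'
#' Empirical alpha-level threshold for the maximum LOD over all scanned
#' markers, from phenotype permutations (the standard genome-wide
#' significance procedure for QTL scans).
#'
#' @param data an [f2_dataset()].
#' @param n_perm permutations (default 1000).
#' @param alpha genome-wide error rate (default 0.05).
#' @param seed integer seed.
#' @return list with `threshold` and the vector of permutation `max_lod`.
#' @export
perm_threshold <- function(data, n_perm = 1000, alpha = 0.05, seed = 1) {
  stopifnot(inherits(data, "f2_dataset"))
  x <- apply(data$geno, 2, geno_to_x)
  z <- apply(data$geno, 2, geno_to_z)
  set.seed(substream_seed(seed, "perm"))
  max_lod <- vapply(seq_len(n_perm), function(i) {
    yp <- sample(data$phenotype)
    max(vapply(seq_len(ncol(x)), function(j) {
      fit_locus(yp, x[, j], z[, j])[["lod"]]
    }, numeric(1)))
  }, numeric(1))
  list(threshold = unname(stats::quantile(max_lod, 1 - alpha, type = 7)),
       max_lod = max_lod)
}
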