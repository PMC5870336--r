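#' Build a genetic map with evenly spaced markers
#'
#' Constructs the coordinate scaffold for the simulator: one or more
#' chromosomes, each carrying SNP markers at a fixed physical spacing, with
#' genetic (cM) positions obtained from a constant recombination rate.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param spacing marker spacing in bp (default 50 kb).
#' @param cm_per_mb genetic-to-physical rate in cM per Mb (default 2.5,
#'   close to the soybean genome-wide average).
#' @return an object of class `genetic_map`: list with `chromosomes`
#'   (data.frame chrom, length) and `markers` (data.frame marker, chrom,
#'   pos, cm).
#' @export
genetic_map <- function(chrom_lengths, spacing = 50000, cm_per_mb = 2.5) {
  stopifnot(length(chrom_lengths) >= 1, all(chrom_lengths > 0), spacing >= 1)
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  markers <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    pos <- seq(spacing, chrom_lengths[[ch]], by = spacing)
    data.frame(
      marker = sprintf("%s_%09d", ch, pos),
      chrom = ch, pos = pos, cm = pos / 1e6 * cm_per_mb,
      stringsAsFactors = FALSE
    )
  }))
  validate_genetic_map(structure(
    list(
      chromosomes = data.frame(chrom = names(chrom_lengths),
                               length = unname(chrom_lengths),
                               stringsAsFactors = FALSE),
      markers = markers
    ),
    class = "genetic_map"
  ))
}

validate_genetic_map <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  if (any(map$chromosomes$length <= 0)) stop("chromosome lengths must be > 0")
  for (ch in unique(map$markers$chrom)) {
    m <- map$markers[map$markers$chrom == ch, ]
    if (is.unsorted(m$pos, strictly = TRUE)) {
      stop("marker positions must be strictly increasing on ", ch)
    }
    if (is.unsorted(m$cm)) stop("cM positions must be non-decreasing on ", ch)
  }
  map
}

#' Specify a single-locus QTL model for the simulated trait
#'
#' The trait model is mu + a*x + d*z + e with x in {+1, 0, -1} for
#' {BB, AB, AA} (B = donor allele), z = 1 for heterozygotes, and
#' e ~ Normal(0, env_sd^2).
#'
#' @param chrom chromosome name carrying the QTL.
#' @param pos QTL physical position in bp.
#' @param a additive effect in trait units (a > 0: donor allele increases
#'   the trait).
#' @param d dominance effect in trait units.
#' @param env_sd environmental (residual) standard deviation, >= 0.
#' @param mu population mean (mid-parent value), default 50 trait units.
#' @return an object of class `qtl_model`.
#' @export
qtl_model <- function(chrom, pos, a, d = 0, env_sd = 0, mu = 50) {
  stopifnot(env_sd >= 0, pos >= 1)
  structure(list(chrom = chrom, pos = pos, a = a, d = d,
                 env_sd = env_sd, mu = mu),
            class = "qtl_model")
}

#' Haldane map function
#'
#' Converts a genetic distance to a recombination fraction assuming no
#' crossover interference: r = (1 - exp(-2 m / 100)) / 2 for m in cM.
#'
#' @param cm genetic distance(s) in centiMorgans.
#' @return recombination fraction(s) in [0, 0.5).
#' @export
haldane_r <- function(cm) (1 - exp(-2 * cm / 100)) / 2

## Simulate one parental gamete per row: loci are a Markov chain along the
## chromosome, switching grandparental origin between adjacent loci with
## probability r (Haldane). Returns an n x m 0/1 matrix (1 = donor allele).
simulate_gametes <- function(n, r_adj) {
  m <- length(r_adj) + 1L
  start <- matrix(stats::rbinom(n, 1L, 0.5), ncol = 1L)
  if (m == 1L) return(start)
  switches <- matrix(stats::rbinom(n * (m - 1L), 1L, rep(r_adj, each = n)),
                     nrow = n)
  (matrix(start, n, m) + cbind(0L, t(apply(switches, 1L, cumsum)))) %% 2L
}

#' Simulate an F2 population from a biparental cross
#'
#' Each individual receives two haplotypes from independent meioses of the F1;
#' recombination between adjacent loci follows the Haldane map function on
#' their cM distance. Phenotypes follow the single-QTL model in `qtl`; the
#' QTL segregates as an (unobserved) extra locus at its map position, so it
#' need not coincide with a marker. Marker genotype frequencies converge to
#' the F2 expectation 1:2:1 (AA:AB:BB).
#'
#' @param map a [genetic_map()].
#' @param qtl a [qtl_model()]; its position must lie on one of the map's
#'   chromosomes.
#' @param n number of F2 individuals (>= 1).
#' @param seed integer seed; meiosis and environmental noise use separate
#'   derived streams.
#' @return an object of class `f2_population`: list with `geno` (n x markers
#'   character matrix, "AA"/"AB"/"BB"), `qtl_geno` (same coding at the QTL),
#'   `phenotype` (numeric n), `map`, `qtl`.
#' @export
simulate_f2 <- function(map, qtl, n, seed = 1) {
  validate_genetic_map(map)
  stopifnot(inherits(qtl, "qtl_model"))
  if (n < 1) stop("n must be >= 1")
  chroms <- map$chromosomes$chrom
  if (!qtl$chrom %in% chroms ||
      qtl$pos > map$chromosomes$length[match(qtl$chrom, chroms)]) {
    stop("QTL position is off the map on chromosome ", qtl$chrom)
  }

  geno_list <- list()
  qtl_dose <- NULL
  for (ch in chroms) {
    mk <- map$markers[map$markers$chrom == ch, ]
    loci_cm <- mk$cm
    labels <- mk$marker
    qtl_here <- identical(ch, qtl$chrom)
    if (qtl_here) {
      # insert the QTL as a pseudo-locus at its interpolated cM position
      cm_per_bp <- if (nrow(mk) >= 2) {
        (mk$cm[nrow(mk)] - mk$cm[1]) / (mk$pos[nrow(mk)] - mk$pos[1])
      } else 2.5e-6
      qtl_cm <- if (nrow(mk) >= 1) {
        mk$cm[1] + (qtl$pos - mk$pos[1]) * cm_per_bp
      } else qtl$pos * 2.5e-6
      ord <- order(c(loci_cm, qtl_cm))
      loci_cm <- c(loci_cm, qtl_cm)[ord]
      labels <- c(labels, ".qtl")[ord]
    }
    set.seed(substream_seed(seed, paste0("meiosis_", ch)))
    r_adj <- haldane_r(diff(loci_cm))
    dose <- simulate_gametes(n, r_adj) + simulate_gametes(n, r_adj)
    colnames(dose) <- labels
    if (qtl_here) {
      qtl_dose <- dose[, labels == ".qtl", drop = TRUE]
      dose <- dose[, labels != ".qtl", drop = FALSE]
    }
    geno_list[[ch]] <- dose
  }
  dose_all <- do.call(cbind, geno_list)
  geno <- matrix(c("AA", "AB", "BB")[dose_all + 1L],
                 nrow = n, dimnames = list(NULL, colnames(dose_all)))

  x <- qtl_dose - 1L           # -1/0/+1 for AA/AB/BB
  z <- as.integer(qtl_dose == 1L)
  set.seed(substream_seed(seed, "phenotype"))
  eps <- if (qtl$env_sd > 0) stats::rnorm(n, 0, qtl$env_sd) else numeric(n)
  phe <- qtl$mu + qtl$a * x + qtl$d * z + eps

  structure(list(geno = geno,
                 qtl_geno = c("AA", "AB", "BB")[qtl_dose + 1L],
                 phenotype = phe, map = map, qtl = qtl, seed = seed),
            class = "f2_population")
}

#' Select the extreme-phenotype bulks from an F2 population
#'
#' Pure rank selection: the `n_high` largest and `n_low` smallest phenotypes
#' form the high and low bulks. Ties are broken by individual index
#' (ascending) so the selection is deterministic.
#'
#' @param pop an `f2_population`.
#' @param n_high,n_low bulk sizes (default 20 each, the study design).
#' @return list with integer index vectors `high_ids` and `low_ids`.
#' @export
make_bulks <- function(pop, n_high = 20, n_low = 20) {
  stopifnot(inherits(pop, "f2_population"), n_high >= 1, n_low >= 1)
  n <- length(pop$phenotype)
  if (n_high + n_low > n) {
    stop("bulk sizes (", n_high, "+", n_low, ") exceed population size ", n)
  }
  idx <- seq_len(n)
  high <- order(-pop$phenotype, idx)[1:n_high]  # ties by ascending index
  low <- order(pop$phenotype, idx)[1:n_low]
  if (length(intersect(high, low)) > 0) {
    stop("high and low bulks overlap; reduce bulk sizes")
  }
  list(high_ids = sort(high), low_ids = sort(low))
}

#' Sample pooled sequencing reads for one bulk
#'
#' Emulates short-read sequencing of a DNA pool at roughly uniform coverage:
#' for each marker the bulk's donor-allele frequency is
#' p = (# B alleles) / (2 * bulk size); read depth is Poisson(`depth_mean`)
#' truncated at >= 1, and the alt (donor) read count is Binomial(depth, p).
#'
#' @param pop an `f2_population`.
#' @param ids indices of the bulked individuals (non-empty).
#' @param depth_mean mean per-SNP coverage (default 10, the study's depth).
#' @param seed integer seed for the read-sampling stream.
#' @return data.frame with chrom, pos, p (true bulk allele frequency),
#'   depth, ref_count, alt_count — one row per marker.
#' @export
sample_bulk_reads <- function(pop, ids, depth_mean = 10, seed = 1) {
  stopifnot(inherits(pop, "f2_population"), length(ids) >= 1, depth_mean > 0)
  g <- pop$geno[ids, , drop = FALSE]
  b_alleles <- colSums((g == "AB") + 2L * (g == "BB"))
  p <- b_alleles / (2 * length(ids))
  m <- length(p)
  set.seed(substream_seed(seed, "reads"))
  depth <- stats::qpois(stats::runif(m, stats::dpois(0, depth_mean), 1),
                        depth_mean)   # zero-truncated Poisson
  alt <- stats::rbinom(m, depth, p)
  mk <- pop$map$markers
  data.frame(chrom = mk$chrom, pos = mk$pos, p = unname(p),
             depth = depth, ref_count = depth - alt, alt_count = alt,
             stringsAsFactors = FALSE)
}

#' Simulate a complete two-bulk QTL-seq experiment
#'
#' Convenience wrapper: simulate the F2, rank-select the bulks, and sample
#' reads for both bulks with independent streams. Returns the variant record
#' table consumed by [apply_filters()] / [snp_index_table()], plus the
#' underlying truth.
#'
#' @inheritParams simulate_f2
#' @param n_high,n_low bulk sizes.
#' @param depth_mean mean per-SNP coverage per bulk.
#' @param qual phred site quality assigned to the synthetic records
#'   (default 60; the generator does not model calling errors).
#' @return list with `records` (bulk_variants data.frame: chrom, pos,
#'   ref_allele, alt_allele, hph_ref, hph_alt, lph_ref, lph_alt, qual),
#'   `pop`, `bulks`, `truth` (QTL position/effects/seed).
#' @export
simulate_qtlseq <- function(map, qtl, n = 349, n_high = 20, n_low = 20,
                            depth_mean = 10, seed = 1, qual = 60) {
  pop <- simulate_f2(map, qtl, n, seed)
  bulks <- make_bulks(pop, n_high, n_low)
  hi <- sample_bulk_reads(pop, bulks$high_ids, depth_mean,
                          substream_seed(seed, "hph"))
  lo <- sample_bulk_reads(pop, bulks$low_ids, depth_mean,
                          substream_seed(seed, "lph"))
  records <- data.frame(
    chrom = hi$chrom, pos = hi$pos,
    ref_allele = "A", alt_allele = "T",
    hph_ref = hi$ref_count, hph_alt = hi$alt_count,
    lph_ref = lo$ref_count, lph_alt = lo$alt_count,
    qual = qual, stringsAsFactors = FALSE
  )
  list(records = records, pop = pop, bulks = bulks,
       truth = list(chrom = qtl$chrom, pos = qtl$pos, a = qtl$a, d = qtl$d,
                    env_sd = qtl$env_sd, mu = qtl$mu, seed = seed))
}

#' Phenotype F2-derived families by progeny means
#'
#' Emulates phenotyping each F2 plant through its selfed family: the family
#' value is the mean of `n_progeny` plants whose expected genotype mixture
#' follows selfing of the F2 genotype, with independent environmental noise
#' per plant. Used to generate replicated family tables for heritability and
#' ANOVA.
#'
#' @param pop an `f2_population`.
#' @param n_progeny plants sampled per family (default 5).
#' @param env_sd per-plant residual SD (defaults to the population model's).
#' @param seed integer seed.
#' @return numeric vector of family means, one per F2 individual.
#' @export
family_means <- function(pop, n_progeny = 5, env_sd = pop$qtl$env_sd,
                         seed = 1) {
  stopifnot(inherits(pop, "f2_population"), n_progeny >= 1)
  qtl <- pop$qtl
  set.seed(substream_seed(seed, "family"))
  vapply(pop$qtl_geno, function(g) {
    dose <- switch(g,
      AA = rep(0L, n_progeny),
      BB = rep(2L, n_progeny),
      AB = stats::rbinom(n_progeny, 2L, 0.5))   # selfing segregation
    x <- dose - 1L
    z <- as.integer(dose == 1L)
    mean(qtl$mu + qtl$a * x + qtl$d * z + stats::rnorm(n_progeny, 0, env_sd))
  }, numeric(1), USE.NAMES = FALSE)
}
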