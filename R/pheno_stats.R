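#' Descriptive phenotype statistics
#'
#' Mean, sample standard deviation (n - 1 denominator), range, and the
#' coefficient of variation CV = 100 * sd / mean.
#'
#' @param values numeric vector (>= 2 values).
#' @return list: mean, sd, min, max, cv_percent (NA with a warning when the
#'   mean is zero).
#' @export
describe <- function(values) {
  stopifnot(length(values) >= 2)
  m <- mean(values)
  s <- stats::sd(values)
  cv <- if (m == 0) {
    warning("mean is zero; CV undefined")
    NA_real_
  } else 100 * s / m
  list(mean = m, sd = s, min = min(values), max = max(values),
       cv_percent = cv)
}

#' Broad-sense heritability from replicated family data
#'
#' One-way random-effects ANOVA of family values over replicates:
#' sigma2_g = (MS_family - MS_error) / r (truncated at 0) with r the
#' replicate count (harmonic mean when unbalanced), and
#' h2 = 100 * sigma2_g / (sigma2_g + MS_error). MS_error estimates the
#' within-family (environmental) variance, so h2 approaches the
#' plot-basis ratio sigma2_g / (sigma2_g + sigma2_e).
#'
#' @param pheno long-format data.frame with columns `family` and `value`
#'   (one row per replicate observation); an optional `environment` column
#'   is subset with `env`.
#' @param env environment name to analyse (default: all rows).
#' @return list: h2_percent, sigma2_g, ms_family, ms_error, r (effective
#'   replicates), n_families.
#' @export
heritability <- function(pheno, env = NULL) {
  if (!is.null(env)) pheno <- pheno[pheno$environment == env, , drop = FALSE]
  counts <- table(pheno$family)
  if (length(counts) < 2) stop("need >= 2 families")
  if (all(counts == 1)) stop("h2 not estimable with a single replicate")
  fit <- stats::aov(value ~ factor(family), data = pheno)
  tab <- summary(fit)[[1]]
  ms_f <- tab["factor(family)", "Mean Sq"]
  ms_e <- tab["Residuals", "Mean Sq"]
  r <- if (length(unique(counts)) == 1) unname(counts[1]) else {
    length(counts) / sum(1 / counts)   # harmonic-mean replicates
  }
  s2g <- max((ms_f - ms_e) / r, 0)
  list(h2_percent = 100 * s2g / (s2g + ms_e), sigma2_g = s2g,
       ms_family = ms_f, ms_error = ms_e, r = r,
       n_families = length(counts))
}

#' Joint two-way ANOVA of genotype and environment
#'
#' Fixed-effects two-way ANOVA with interaction (genotype, environment,
#' genotype x environment, error); the sums of squares partition the total
#' exactly. Every family must be observed in every environment.
#'
#' @param pheno long-format data.frame with columns family, environment,
#'   value (one row per replicate observation).
#' @return data.frame (source, df, ss, ms, f, p) with rows G, E, GxE,
#'   error.
#' @export
joint_anova <- function(pheno) {
  tab <- table(pheno$family, pheno$environment)
  if (any(tab == 0)) {
    miss <- which(tab == 0, arr.ind = TRUE)
    stop("missing family x environment cells: ",
         paste(rownames(tab)[miss[, 1]], colnames(tab)[miss[, 2]],
               sep = "/", collapse = ", "))
  }
  fit <- stats::aov(value ~ factor(family) * factor(environment),
                    data = pheno)
  a <- summary(fit)[[1]]
  out <- data.frame(
    source = c("G", "E", "GxE", "error"),
    df = a[["Df"]], ss = a[["Sum Sq"]], ms = a[["Mean Sq"]],
    f = a[["F value"]], p = a[["Pr(>F)"]],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Simulate a replicated family phenotype table
#'
#' Families receive independent genetic effects ~ Normal(0, sigma2_g) and
#' each replicate observation adds noise ~ Normal(0, sigma2_e); used to
#' calibrate the heritability and ANOVA estimators against known variance
#' components.
#'
#' @param n_families,n_reps design size.
#' @param sigma2_g,sigma2_e genetic and residual variances.
#' @param mu grand mean.
#' @param environments character vector of environment names; each gets an
#'   independent additive shift ~ Normal(0, sigma2_env).
#' @param sigma2_env between-environment variance (default 0).
#' @param seed integer seed.
#' @return long-format data.frame: family, environment, replicate, value.
#' @export
simulate_families <- function(n_families = 300, n_reps = 3, sigma2_g = 8,
                              sigma2_e = 2, mu = 50,
                              environments = "E1", sigma2_env = 0,
                              seed = 1) {
  set.seed(substream_seed(seed, "families"))
  g <- stats::rnorm(n_families, 0, sqrt(sigma2_g))
  env_eff <- stats::rnorm(length(environments), 0, sqrt(sigma2_env))
  grid <- expand.grid(family = seq_len(n_families),
                      environment = environments,
                      replicate = seq_len(n_reps),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$value <- mu + g[grid$family] +
    env_eff[match(grid$environment, environments)] +
    stats::rnorm(nrow(grid), 0, sqrt(sigma2_e))
  grid
}
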