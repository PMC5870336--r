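make_scan_data <- function(n = 30, seed = 1, a = 3, d = 1, sd = 0,
                           mu = 50) {
  set.seed(seed)
  g <- sample(c("AA", "AB", "BB"), n, replace = TRUE,
              prob = c(0.25, 0.5, 0.25))
  x <- c(AA = -1, AB = 0, BB = 1)[g]
  z <- as.numeric(g == "AB")
  y <- mu + a * x + d * z + rnorm(n, 0, sd)
  geno <- matrix(g, ncol = 1, dimnames = list(NULL, "m1"))
  f2_dataset(geno, y, data.frame(marker = "m1", chrom = "chr1",
                                 pos = 1e5, cm = 0.25))
}

test_that("a noise-free genetic model is recovered exactly", {
  ds <- make_scan_data(a = 3, d = 1, sd = 0)
  sc <- scan_markers(ds)
  expect_equal(sc$a, 3)
  expect_equal(sc$d, 1)
  expect_equal(sc$r2, 100)
  expect_true(is.infinite(sc$lod) || sc$lod > 10)
})

test_that("permuted phenotypes give near-zero LOD", {
  ds <- make_scan_data(n = 349, a = 2, d = 0.4, sd = 3)
  set.seed(5)
  lods <- replicate(200, {
    scan_markers(f2_dataset(ds$geno, sample(ds$phenotype), ds$map))$lod
  })
  expect_lt(mean(lods), 0.5)
})

test_that("simulated F2 effect estimates are unbiased within Monte-Carlo error", {
  map <- genetic_map(c(chr1 = 2e6), spacing = 1e6)
  est <- t(sapply(1:50, function(s) {
    pop <- simulate_f2(map, qtl_model("chr1", 1e6, a = 2, d = 0.4,
                                      env_sd = 3), 349, seed = s)
    sc <- scan_markers(as_f2_dataset(pop))
    unlist(sc[which.max(sc$lod), c("a", "d")])
  }))
  se_a <- sd(est[, "a"]) / sqrt(nrow(est))
  se_d <- sd(est[, "d"]) / sqrt(nrow(est))
  expect_lt(abs(mean(est[, "a"]) - 2), 3 * se_a)
  expect_lt(abs(mean(est[, "d"]) - 0.4), 3 * se_d)
})

test_that("LOD and R2 are invariant to affine phenotype rescaling", {
  ds <- make_scan_data(n = 200, a = 2, d = 0.5, sd = 2)
  sc1 <- scan_markers(ds)
  ds2 <- f2_dataset(ds$geno, 3.7 * ds$phenotype - 12, ds$map)
  sc2 <- scan_markers(ds2)
  expect_equal(sc1$lod, sc2$lod)
  expect_equal(sc1$r2, sc2$r2)
  expect_equal(3.7 * sc1$a, sc2$a)
})

test_that("missing genotypes are dropped casewise and thin markers skipped", {
  ds <- make_scan_data(n = 100, sd = 1)
  g <- ds$geno
  g[1:20, 1] <- NA
  sc <- scan_markers(f2_dataset(g, ds$phenotype, ds$map))
  expect_equal(sc$n_used, 80)
  g[1:95, 1] <- NA
  expect_warning(
    out <- scan_markers(f2_dataset(g, ds$phenotype, ds$map)), "skipped")
  expect_null(out)
})

test_that("a monomorphic dominance class falls back to the reduced model", {
  g <- matrix(rep(c("AA", "BB"), each = 15), ncol = 1,
              dimnames = list(NULL, "m1"))
  y <- c(rep(47, 15), rep(53, 15))
  ds <- f2_dataset(g, y, data.frame(marker = "m1", chrom = "c", pos = 1,
                                    cm = 0))
  sc <- scan_markers(ds)
  expect_equal(sc$a, 3)
  expect_true(is.na(sc$d))
  expect_equal(sc$reduced, 1)
})

test_that("interval scan agrees with the marker scan at marker positions", {
  map <- genetic_map(c(chr1 = 8e6), spacing = 4e6)
  pop <- simulate_f2(map, qtl_model("chr1", 6e6, a = 3, d = 0, env_sd = 3),
                     349, seed = 1)
  ds <- as_f2_dataset(pop)
  si <- scan_interval(ds, step_cm = 1)
  sm <- scan_markers(ds)
  at_markers <- si[!is.na(si$marker), ]
  expect_equal(at_markers$lod, sm$lod[match(at_markers$marker, sm$marker)])
  expect_equal(at_markers$a, sm$a[match(at_markers$marker, sm$marker)])
})

test_that("a QTL midway between flanking markers peaks inside the interval", {
  map <- genetic_map(c(chr1 = 8e6), spacing = 4e6)  # flanks 10 cM apart
  hits <- sapply(1:50, function(s) {
    pop <- simulate_f2(map, qtl_model("chr1", 6e6, a = 3, d = 0, env_sd = 3),
                       349, seed = s)
    sc <- scan_interval(as_f2_dataset(pop), step_cm = 1)
    max(sc$lod[is.na(sc$marker)]) > max(sc$lod[!is.na(sc$marker)])
  })
  expect_gte(mean(hits), 0.8)
})

test_that("zero recombination between flanks gives a flat interior profile", {
  map <- structure(list(
    chromosomes = data.frame(chrom = "chr1", length = 3e6),
    markers = data.frame(marker = c("m1", "m2"), chrom = "chr1",
                         pos = c(1e6, 2e6), cm = c(5, 5))
  ), class = "genetic_map")
  pop <- simulate_f2(map, qtl_model("chr1", 1e6, a = 2, env_sd = 2), 200,
                     seed = 2)
  ds <- as_f2_dataset(pop)
  # grid collapses to the shared cM position: scan falls back to markers
  sc <- scan_interval(ds, step_cm = 1)
  expect_true(all(abs(diff(sc$lod)) < 1e-9))
})

test_that("single-marker chromosomes fall back to the marker scan", {
  ds <- make_scan_data(n = 50, sd = 1)
  si <- scan_interval(ds)
  sm <- scan_markers(ds)
  expect_equal(si$lod, sm$lod)
})

test_that("permutation threshold is reproducible and above typical null LOD", {
  map <- genetic_map(c(chr1 = 4e6), spacing = 1e6)
  pop <- simulate_f2(map, qtl_model("chr1", 2e6, a = 0, env_sd = 3), 150,
                     seed = 3)
  ds <- as_f2_dataset(pop)
  p1 <- perm_threshold(ds, n_perm = 100, seed = 4)
  p2 <- perm_threshold(ds, n_perm = 100, seed = 4)
  expect_identical(p1$threshold, p2$threshold)
  expect_gt(p1$threshold, 0.5)
  expect_lt(p1$threshold, 5)
})
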