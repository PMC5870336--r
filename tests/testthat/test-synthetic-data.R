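test_that("noise-free additive phenotypes take exactly the three genotype values", {
  map <- genetic_map(c(chr1 = 1e6), spacing = 2e5)
  pop <- simulate_f2(map, qtl_model("chr1", 5e5, a = 5, d = 0, env_sd = 0),
                     n = 200, seed = 1)
  expect_setequal(unique(pop$phenotype), c(45, 50, 55))
  # genotype at the QTL determines the value exactly
  expect_equal(pop$phenotype,
               c(AA = 45, AB = 50, BB = 55)[pop$qtl_geno],
               ignore_attr = TRUE)
})

test_that("marker genotype frequencies converge to 1:2:1 within binomial error", {
  map <- genetic_map(c(chr1 = 1e6), spacing = 2e5)
  n <- 10000
  pop <- simulate_f2(map, qtl_model("chr1", 5e5, a = 1, env_sd = 1), n,
                     seed = 42)
  for (j in seq_len(ncol(pop$geno))) {
    freq <- table(factor(pop$geno[, j], levels = c("AA", "AB", "BB"))) / n
    expected <- c(0.25, 0.5, 0.25)
    se <- sqrt(expected * (1 - expected) / n)
    expect_true(all(abs(freq - expected) < 3 * se))
  }
})

test_that("F2 segregation passes a 1:2:1 chi-square test across seeds", {
  map <- genetic_map(c(chr1 = 4e5), spacing = 2e5)
  pvals <- sapply(1:20, function(s) {
    pop <- simulate_f2(map, qtl_model("chr1", 1e5, a = 0, env_sd = 1), 5000,
                       seed = s)
    counts <- table(factor(pop$geno[, 1], levels = c("AA", "AB", "BB")))
    suppressWarnings(chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value)
  })
  expect_true(all(pvals > 0.001))
})

test_that("recombinant fractions follow the Haldane map function", {
  # markers at cM distances 1, 10, 50 from the first locus
  cm <- c(0, 1, 10, 50)
  pos <- c(1e4, 2e4, 3e4, 4e4)
  map <- structure(list(
    chromosomes = data.frame(chrom = "chr1", length = 5e4),
    markers = data.frame(marker = paste0("m", 1:4), chrom = "chr1",
                         pos = pos, cm = cm)
  ), class = "genetic_map")
  n <- 8000
  pop <- simulate_f2(map, qtl_model("chr1", 1e4, a = 0, env_sd = 1), n,
                     seed = 7)
  dose <- matrix(match(pop$geno, c("AA", "AB", "BB")) - 1L, nrow = n)
  # gamete-level recombinant fraction between locus 1 and locus j is not
  # directly observable from genotypes; compare adjacent-interval switch
  # rates on single gametes instead, via haploid doses of homozygotes at m1
  for (j in 2:4) {
    m <- cm[j] - cm[1]
    r <- haldane_r(m)
    # among individuals homozygous at m1, P(heterozygous or opposite
    # homozygote at mj) follows from two independent gametes with
    # recombination r: P(recomb genotype pattern) = 2r(1-r) + r^2 ... use
    # expected dose correlation instead: cor(dose1, dosej) = (1 - 2r)
    obs <- cor(dose[, 1], dose[, j])
    se <- 1 / sqrt(n)   # conservative large-sample SE of a correlation
    expect_true(abs(obs - (1 - 2 * r)) < 3 * se,
                label = sprintf("cor at %g cM: %.3f vs %.3f", m, obs, 1 - 2 * r))
  }
})

test_that("markers 0 cM apart show zero recombinants", {
  map <- structure(list(
    chromosomes = data.frame(chrom = "chr1", length = 3e4),
    markers = data.frame(marker = c("m1", "m2"), chrom = "chr1",
                         pos = c(1e4, 2e4), cm = c(5, 5))
  ), class = "genetic_map")
  pop <- simulate_f2(map, qtl_model("chr1", 1e4, a = 0, env_sd = 1), 500,
                     seed = 3)
  expect_identical(pop$geno[, 1], pop$geno[, 2])
})

test_that("QTL off the map and invalid n are rejected", {
  map <- genetic_map(c(chrA = 1e6))
  expect_error(simulate_f2(map, qtl_model("chrB", 5e5, a = 1), 10), "chrB")
  expect_error(simulate_f2(map, qtl_model("chrA", 2e6, a = 1), 10), "chrA")
  expect_error(simulate_f2(map, qtl_model("chrA", 5e5, a = 1), 0), "n must be")
})

test_that("bulk selection is a deterministic rank split", {
  geno <- matrix("AB", 40, 2)
  pop <- fixed_population(geno, phenotype = 1:40)
  b <- make_bulks(pop, n_high = 20, n_low = 20)
  expect_identical(b$high_ids, 21:40)
  expect_identical(b$low_ids, 1:20)
  b1 <- make_bulks(pop, n_high = 1, n_low = 1)
  expect_identical(b1$high_ids, 40L)
  expect_identical(b1$low_ids, 1L)
  expect_error(make_bulks(pop, 30, 30), "exceed")
})

test_that("bulks are enriched for the causal allele under an additive QTL", {
  map <- genetic_map(c(chr1 = 1e6), spacing = 1e5)
  pop <- simulate_f2(map, qtl_model("chr1", 5e5, a = 4, d = 0, env_sd = 0.5),
                     n = 349, seed = 11)
  b <- make_bulks(pop, 20, 20)
  freq_b <- function(ids) {
    g <- pop$qtl_geno[ids]
    (sum(g == "AB") + 2 * sum(g == "BB")) / (2 * length(ids))
  }
  expect_gt(freq_b(b$high_ids), 0.5)
  expect_lt(freq_b(b$low_ids), 0.5)
  expect_length(intersect(b$high_ids, b$low_ids), 0)
})

test_that("bulk read sampling reflects the pooled allele frequency", {
  # all AA -> no alt reads; all BB -> all alt reads
  pop_aa <- fixed_population(matrix("AA", 5, 10))
  r_aa <- sample_bulk_reads(pop_aa, 1:5, depth_mean = 8, seed = 1)
  expect_true(all(r_aa$alt_count == 0))
  pop_bb <- fixed_population(matrix("BB", 5, 10))
  r_bb <- sample_bulk_reads(pop_bb, 1:5, depth_mean = 8, seed = 1)
  expect_true(all(r_bb$alt_count == r_bb$depth))
  expect_true(all(r_aa$depth >= 1))
})

test_that("mean SNP-index is 0.5 at p = 0.5 over many markers", {
  pop <- fixed_population(matrix("AB", 1, 1e5), spacing = 100)
  r <- sample_bulk_reads(pop, 1, depth_mean = 10, seed = 5)
  idx <- r$alt_count / r$depth
  se <- sd(idx) / sqrt(length(idx))
  expect_lt(abs(mean(idx) - 0.5), 3 * se)
})

test_that("family means track the F2 genotype under selfing", {
  map <- genetic_map(c(chr1 = 1e6), spacing = 2e5)
  pop <- simulate_f2(map, qtl_model("chr1", 5e5, a = 5, d = 0, env_sd = 0),
                     n = 300, seed = 2)
  fm <- family_means(pop, n_progeny = 200, env_sd = 0, seed = 1)
  # selfed AA/BB families stay at the homozygote mean; AB families revert
  # toward the population mean (expected dose preserved)
  expect_equal(unname(fm[pop$qtl_geno == "AA"][1]), 45)
  expect_equal(unname(fm[pop$qtl_geno == "BB"][1]), 55)
  het <- fm[pop$qtl_geno == "AB"]
  expect_lt(abs(mean(het) - 50), 1)
})
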