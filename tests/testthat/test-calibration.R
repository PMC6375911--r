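# Rate and size scaling arithmetic, Poisson locus-class calibration, and
# haplotype subsampling.

test_that("per-generation rate arithmetic is exact and linear", {
  expect_equal(per_generation_rate(1.6e-3, 6), 9.6e-9, tolerance = 1e-12)
  expect_equal(per_generation_rate(1e-6, 1), 1e-12, tolerance = 1e-12)
  # linearity in both arguments
  expect_equal(per_generation_rate(2 * 1.3e-3, 5),
               2 * per_generation_rate(1.3e-3, 5))
  expect_equal(per_generation_rate(1.3e-3, 2 * 5),
               2 * per_generation_rate(1.3e-3, 5))
  expect_error(per_generation_rate(0, 6), "positive")
})

test_that("Poisson fit recovers lambda and passes GOF on Poisson data", {
  expect_equal(fit_poisson_snp_counts(rep(0L, 10))$lambda, 0)
  expect_error(fit_poisson_snp_counts(integer(0)), "empty")
  expect_error(fit_poisson_snp_counts(c(1, -2)), "nonnegative")

  set.seed(1234)
  x <- rpois(50000, 1.3)
  fp <- fit_poisson_snp_counts(x)
  expect_lt(abs(fp$lambda - 1.3) / 1.3, 0.01)
  expect_gt(fp$p_value, 0.01)
})

test_that("class rates and weighted averages follow S * mu / lambda", {
  mu <- 9.6e-9
  expect_equal(class_rate(1.3, 1.3, mu), mu)      # S = lambda identity
  expect_equal(class_rate(4, 1.3, mu), 4 * mu / 1.3, tolerance = 1e-12)
  expect_equal(class_rate(4, 1.3, mu), 2.953846e-8, tolerance = 1e-6)
  expect_error(class_rate(4, 0, mu), "lambda")

  # truncated-Poisson weights on S in {4,5,6}
  S <- 4:6
  w <- dpois(S, 1.3)
  mu_hat <- weighted_average(class_rate(S, 1.3, mu), w)
  expect_equal(mu_hat, sum(S * mu / 1.3 * w) / sum(w), tolerance = 1e-12)
  expect_lt(abs(mu_hat - 3.16e-8) / 3.16e-8, 0.01)

  # full-pmf identity: sum_S S P(S) / lambda = 1 recovers mu exactly
  S_all <- 0:60
  w_all <- dpois(S_all, 1.3)
  expect_equal(weighted_average(class_rate(S_all, 1.3, mu), w_all), mu,
               tolerance = 1e-12)
})

test_that("Theta and M scale to effective sizes and migrant numbers", {
  expect_equal(scale_theta(0.00697, 3.55e-8), 49084.51, tolerance = 1e-6)
  expect_equal(scale_theta(4 * 9.6e-9, 9.6e-9), 1)
  expect_equal(scale_migrants(0.00697, 2075), 3.6156875, tolerance = 1e-9)
  expect_error(scale_theta(-1, 1e-8), "positive")
})

test_that("haplotype subsampling is unbiased and deterministic where it must be", {
  # all-homozygous matrix: output independent of the seed
  g <- matrix(c(0L, 2L, 0L, 2L), 2, 2)
  gm <- toy_genotypes(g, c("a", "a"))
  h1 <- subsample_haplotypes(gm, seed = 1)
  h2 <- subsample_haplotypes(gm, seed = 999)
  expect_identical(h1$geno, h2$geno)
  expect_equal(unname(h1$geno), matrix(c(0L, 1L, 0L, 1L), 2, 2))

  # heterozygote draws are fair across seeds
  het <- toy_genotypes(matrix(1L, 1, 1), "a")
  draws <- vapply(1:4000, function(s)
    subsample_haplotypes(het, seed = s)$geno[1, 1], integer(1))
  expect_lt(abs(mean(draws) - 0.5), 0.02)

  # allele frequencies are unbiased relative to the diploid panel
  cfg <- coalescent_config(16, N = 1200, mu = 2e-6, n_loci = 1200, seed = 61)
  gm <- simulate_snp_panel(cfg)
  p_dip <- colMeans(gm$geno) / 2
  p_hap <- rowMeans(vapply(1:20, function(s)
    colMeans(subsample_haplotypes(gm, seed = s)$geno), numeric(ncol(gm$geno))))
  expect_lt(mean(abs(p_hap - p_dip)), 0.04)
  expect_lt(abs(mean(p_hap - p_dip)), 0.005)

  # missing stays missing
  gmna <- toy_genotypes(matrix(c(1L, NA), 1, 2), "a")
  expect_true(is.na(subsample_haplotypes(gmna, seed = 1)$geno[1, 2]))
})
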