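# The structured-coalescent generator: textbook expectations, structural
# constraints, determinism, and the statistical structure of the panels.

test_that("single-deme TMRCA matches the textbook coalescent expectation", {
  N <- 500
  cfg <- coalescent_config(2, N = N, seed = 11)
  tm <- vapply(seq_len(2500), function(i) tmrca(simulate_genealogy(cfg, i)),
               numeric(1))
  # E[TMRCA] = 2N generations for a sample of two
  se <- stats::sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 2 * N), 3 * se)
})

test_that("without migration, cross-deme coalescences happen after T0", {
  cfg <- coalescent_config(c(4, 4), N = c(300, 300), T0 = 800, seed = 5)
  for (i in 1:40) {
    g <- simulate_genealogy(cfg, i)
    n <- g$n_tips
    # nodes whose descendant tips span both demes
    desc <- vector("list", 2 * n - 1)
    for (k in seq_len(n)) desc[[k]] <- k
    for (k in seq_len(2 * n - 2)) {
      p <- g$parent[k]
      desc[[p]] <- c(desc[[p]], desc[[k]])
    }
    tip_deme <- g$deme[seq_len(n)]
    for (k in (n + 1):(2 * n - 1)) {
      if (length(unique(tip_deme[desc[[k]]])) > 1)
        expect_gt(g$time[k], 800)
    }
  }
})

test_that("genealogies are ultrametric with increasing coalescence times", {
  cfg <- coalescent_config(c(6, 4), N = c(200, 100),
                           M = matrix(c(0, 1e-3, 1e-3, 0), 2), T0 = 5000,
                           seed = 9)
  g <- simulate_genealogy(cfg, 3)
  n <- g$n_tips
  expect_equal(g$time[seq_len(n)], rep(0, n))
  internal <- g$time[(n + 1):(2 * n - 1)]
  expect_true(all(diff(internal) > 0))
  has_parent <- g$parent > 0
  expect_true(all(g$time[g$parent[has_parent]] > g$time[has_parent]))
  expect_identical(simulate_genealogy(cfg, 3)[c("parent", "time")],
                   g[c("parent", "time")])   # same (seed, locus) reproduces
  g2 <- simulate_genealogy(cfg, 4)
  expect_false(identical(g2$time, g$time))   # different locus differs
})

test_that("mu = 0 yields zero SNPs and seeds reproduce panels exactly", {
  cfg0 <- coalescent_config(c(4, 4), N = c(100, 100), T0 = 500, mu = 0,
                            n_loci = 50, seed = 3)
  expect_equal(ncol(simulate_snp_panel(cfg0)$geno), 0L)

  cfg <- coalescent_config(c(6, 6), N = c(500, 500), T0 = 2000, mu = 1e-6,
                           n_loci = 300, seed = 21)
  a <- simulate_snp_panel(cfg)
  b <- simulate_snp_panel(cfg)
  expect_identical(a$geno, b$geno)
  cfg2 <- cfg; cfg2$seed <- 22L
  expect_false(identical(simulate_snp_panel(cfg2)$geno, a$geno))
})

test_that("panmictic panel diversity matches theta = 4 N mu per site", {
  N <- 2000; mu <- 1e-6; L <- 95
  cfg <- coalescent_config(20, N = N, mu = mu, locus_length = L,
                           n_loci = 12000, seed = 77)
  gm <- simulate_snp_panel(cfg)
  ss <- snp_summary(gm, total_sites = 12000 * L)
  theta <- 4 * N * mu
  expect_lt(abs(ss$pi - theta) / theta, 0.05)
  # Watterson check through segregating sites: E[S] = theta L a_{n-1} per locus
  a_n <- sum(1 / seq_len(19))
  expect_lt(abs(ss$S - 12000 * theta * L * a_n) / (12000 * theta * L * a_n), 0.05)
})

test_that("SNP counts per locus are Poisson-like", {
  N <- 2000; mu <- 1e-6; L <- 95
  cfg <- coalescent_config(12, N = N, mu = mu, locus_length = L,
                           n_loci = 20000, seed = 13)
  gm <- simulate_snp_panel(cfg)
  counts <- tabulate(factor(gm$locus_id,
                            levels = paste0("locus_", seq_len(20000))))
  fp <- fit_poisson_snp_counts(counts)
  # mean close to mu * L * E[total length]; E[L_tot] = 4N a_{n-1}
  exp_mean <- mu * L * 4 * N * sum(1 / seq_len(11))
  expect_lt(abs(fp$lambda - exp_mean) / exp_mean, 0.25)
  # genealogy-to-genealogy length variation overdisperses the marginal
  # count distribution, so only a loose GOF sanity bound applies here
  expect_true(is.finite(fp$chisq))
})

test_that("complete isolation drives Fst to fixation", {
  cfg <- coalescent_config(c(10, 10), N = c(500, 500), T0 = 20 * 2 * 500,
                           mu = 5e-6, n_loci = 800, seed = 31)
  gm <- simulate_snp_panel(cfg)
  expect_gt(wc_fst(gm), 0.9)
})

test_that("dropout and missingness behave as specified", {
  cfg <- coalescent_config(c(12, 12), N = c(800, 800),
                           M = matrix(c(0, 1e-3, 1e-3, 0), 2), T0 = 5000,
                           mu = 2e-6, n_loci = 1500, seed = 41)
  gm <- simulate_snp_panel(cfg)

  # identity at zero rates
  same <- apply_dropout_and_missingness(gm, 0, 0, seed = 1)
  expect_identical(same$geno, gm$geno)

  # full dropout removes every heterozygote
  gone <- apply_dropout_and_missingness(gm, 1, 0, seed = 1)
  expect_equal(sum(gone$geno == 1L, na.rm = TRUE), 0L)

  # dropout_rate = 0.2 keeps ~80% of heterozygotes (enumeration oracle:
  # each het survives iff its individual-locus was not hit)
  h0 <- mean(gm$geno == 1L, na.rm = TRUE)
  hs <- vapply(1:12, function(s)
    mean(apply_dropout_and_missingness(gm, 0.2, 0, seed = s)$geno == 1L,
         na.rm = TRUE), numeric(1))
  expect_lt(abs(mean(hs) - 0.8 * h0) / (0.8 * h0), 0.05)

  # missingness applies per individual-locus
  mm <- apply_dropout_and_missingness(gm, 0, 0.3, seed = 2)
  expect_lt(abs(mean(is.na(mm$geno)) - 0.3), 0.05)
  # deterministic given seed
  mm2 <- apply_dropout_and_missingness(gm, 0, 0.3, seed = 2)
  expect_identical(mm$geno, mm2$geno)
})

test_that("mtDNA generator hits the Watterson scale and panmixia/isolation limits", {
  # E[S] targeting: one colony, theta tuned for E[S] ~ 14 on 900 bp, n = 109
  n <- 109; L <- 900
  a_n <- sum(1 / seq_len(n - 1))
  theta <- 14 / (L * a_n)
  S <- vapply(1:25, function(s) {
    a <- simulate_mtdna_colonies(c(one = n), theta, 0, L, seed = 600 + s)
    summary_stats(a)$S
  }, numeric(1))
  expect_lt(abs(mean(S) - 14) / 14, 0.25)

  # strong migration: pairwise Phi_ST near zero on average
  phis <- vapply(1:10, function(s) {
    a <- simulate_mtdna_colonies(c(x = 12, y = 12), 5e-4,
                                 matrix(c(0, 500, 500, 0), 2), 900,
                                 seed = 700 + s)
    phi_st(a, "x", "y", n_permutations = 0)$phi_st
  }, numeric(1))
  expect_lt(abs(mean(phis)), 0.05)

  # no migration, deep divergence: Phi_ST -> 1
  a <- simulate_mtdna_colonies(c(x = 12, y = 12), 1e-3, 0, 900, seed = 8,
                               divergence = 50)
  expect_gt(phi_st(a, "x", "y", n_permutations = 0)$phi_st, 0.9)
})
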