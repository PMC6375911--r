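# Summary statistics, Phi_ST, AMOVA and multiple-testing correction against
# independent oracles.

test_that("pairwise differences equal the column-scan oracle", {
  aln <- toy_alignment(c("ACGTACGTAC", "ACGTACGTAC"), c("a", "a"))
  expect_true(all(pairwise_differences(aln) == 0))

  s1 <- paste(rep("A", 100), collapse = "")
  s2 <- paste(c(rep("A", 97), "C", "G", "T"), collapse = "")
  aln <- toy_alignment(c(s1, s2), c("a", "a"))
  expect_equal(pairwise_differences(aln)[1, 2], 3)

  # an N in one sequence excludes that site from the pair's comparison
  a <- "ACGTACGT"
  b <- "NCGTACGA"  # one N, one real difference
  aln <- toy_alignment(c(a, b), c("a", "a"))
  expect_equal(pairwise_differences(aln)[1, 2], oracle_hamming(a, b))
  expect_equal(pairwise_differences(aln)[1, 2], 1)

  set.seed(3)
  seqs <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T", "N"), 40, TRUE,
                 prob = c(.24, .24, .24, .24, .04)), collapse = ""),
    character(1))
  aln <- toy_alignment(seqs, rep("a", 5))
  d <- pairwise_differences(aln)
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(d[i, j], oracle_hamming(seqs[i], seqs[j]))
})

test_that("summary statistics match their defining formulas", {
  aln <- toy_alignment(rep("ACGTACGT", 3), rep("a", 3))
  st <- summary_stats(aln)
  expect_equal(st$H, 0)
  expect_equal(st$pi, 0)
  expect_equal(st$K, 0)
  expect_equal(st$S, 0L)
  expect_true(is.nan(st$D))

  expect_error(summary_stats(toy_alignment("ACGT", "a")), "two sequences")

  # n = 4, S = 3, K = 1.5 gives D ~ -0.754 under the standard constants
  expect_equal(oracle_tajima_d(3, 1.5, 4), -0.754, tolerance = 1e-3)
  seqs <- c("AAAA", "AAAC", "AAGA", "ATAA")  # S = 3, K = 1.5 by enumeration
  st <- summary_stats(toy_alignment(seqs, rep("a", 4)))
  expect_equal(st$S, 3L)
  expect_equal(st$K, 1.5)
  expect_equal(st$D, oracle_tajima_d(3, 1.5, 4), tolerance = 1e-9)

  # unbiased haplotype diversity: 4 distinct haplotypes in n = 4
  expect_equal(st$H, 4 / 3 * (1 - 4 * (1 / 4)^2))
})

test_that("SNP-matrix Tajima's D agrees with the formula oracle and is ~0 under neutrality", {
  # toy 5-SNP matrix, no missingness: D must equal the S/K formula exactly
  g <- rbind(c(0L, 1L, 0L, 2L, 1L),
             c(1L, 1L, 0L, 2L, 0L),
             c(0L, 0L, 1L, 1L, 0L),
             c(2L, 1L, 0L, 0L, 1L))
  gm <- toy_genotypes(g, rep("P", 4))
  n <- 8 # haploids
  p <- colSums(g) / n
  K <- sum(n / (n - 1) * 2 * p * (1 - p))
  expect_equal(tajimas_d_snp(gm, total_sites = 5 * 95),
               oracle_tajima_d(5, K, n), tolerance = 1e-9)

  expect_true(is.nan(tajimas_d_snp(toy_genotypes(matrix(0L, 4, 3), rep("P", 4)),
                                   total_sites = 100)))
  expect_error(snp_summary(gm), "total_sites")

  # neutral constant-size panels: mean D near zero over replicates
  d <- vapply(1:8, function(s) {
    cfg <- coalescent_config(16, N = 1500, mu = 2e-6, n_loci = 3000,
                             seed = 900 + s)
    tajimas_d_snp(simulate_snp_panel(cfg), total_sites = 3000 * 95)
  }, numeric(1))
  expect_lt(abs(mean(d)), 2 * stats::sd(d) / sqrt(length(d)) + 0.15)
})

test_that("pairwise Phi_ST matches fixation, panmixia and the enumeration oracle", {
  # two populations fixed for distinct haplotypes
  aln <- toy_alignment(c("AAAA", "AAAA", "TTTT", "TTTT"),
                       c("x", "x", "y", "y"))
  expect_equal(phi_st(aln, "x", "y", n_permutations = 0)$phi_st, 1)

  # a shuffled pool gives Phi_ST ~ 0 on average
  set.seed(5)
  pool <- simulate_mtdna_colonies(c(p = 24), 5e-3, 0, 400, seed = 44)
  phis <- vapply(1:30, function(i) {
    lab <- sample(rep(c("x", "y"), each = 12))
    a <- hap_alignment(pool$ids, apply(pool$seq, 1, paste0, collapse = ""),
                       lab, lab)
    phi_st(a, "x", "y", n_permutations = 0)$phi_st
  }, numeric(1))
  expect_lt(abs(mean(phis)), 0.03)

  # 6-sequence toy set against the brute-force sums-of-squares oracle
  seqs <- c("AACGT", "AACGA", "ATCGA", "TTCGA", "TTGGA", "TTGGT")
  aln <- toy_alignment(seqs, c("x", "x", "x", "y", "y", "y"))
  r <- phi_st(aln, "x", "y", n_permutations = 0)
  o <- oracle_amova2(pairwise_differences(aln), c(1, 1, 1, 2, 2, 2))
  expect_equal(r$phi_st, o$phi_st, tolerance = 1e-9)
  expect_equal(unname(r$sigma2), unname(o$sigma2), tolerance = 1e-9)

  expect_error(phi_st(aln, "x", "zz"), "zz")

  # symmetry: relabeling populations and permuting sequence order
  r2 <- phi_st(aln, "y", "x", n_permutations = 0)
  expect_equal(r2$phi_st, r$phi_st, tolerance = 1e-12)
  ord <- c(4, 2, 6, 1, 3, 5)
  aln2 <- toy_alignment(seqs[ord], c("x", "x", "x", "y", "y", "y")[ord],
                        ids = paste0("t", 1:6))
  expect_equal(phi_st(aln2, "x", "y", n_permutations = 0)$phi_st, r$phi_st,
               tolerance = 1e-12)
})

test_that("three-level AMOVA equals the enumeration oracle and sums to 100%", {
  # 2 groups x 2 colonies x 3 samples
  set.seed(8)
  aln <- simulate_mtdna_colonies(c(c1 = 3, c2 = 3, c3 = 3, c4 = 3), 8e-4,
                                 matrix(2, 4, 4), 500, seed = 55,
                                 groups = c(c1 = "g1", c2 = "g1",
                                            c3 = "g2", c4 = "g2"))
  am <- amova(aln, n_permutations = 99, seed = 1)
  d2 <- pairwise_differences(aln)
  pop <- match(aln$colony, unique(aln$colony))
  o <- oracle_amova3(d2, pop, c(1, 1, 2, 2))
  expect_equal(unname(am$sigma2), o$sigma2, tolerance = 1e-9)
  expect_equal(unname(am$phi),
               c(o$phi_st, o$phi_sc, o$phi_ct), tolerance = 1e-9)
  expect_equal(sum(am$percent), 100, tolerance = 1e-6)
  # Phi identities on the components
  s <- am$sigma2
  expect_equal(am$phi[["phi_st"]] * sum(s), s[[1]] + s[[2]], tolerance = 1e-9)
  expect_equal(am$phi[["phi_sc"]], s[[2]] / (s[[2]] + s[[3]]), tolerance = 1e-12)

  # all-identical sequences: zero components, undefined Phi
  same <- toy_alignment(rep("ACGT", 8), rep(c("c1", "c2", "c3", "c4"), each = 2),
                        rep(c("g1", "g1", "g2", "g2"), each = 2))
  am0 <- amova(same, n_permutations = 0)
  expect_equal(unname(am0$sigma2), c(0, 0, 0))
  expect_true(all(is.nan(am0$phi)))

  expect_error(amova(toy_alignment(c("AC", "AG"), c("x", "y"), c("g", "g"))),
               "two groups")
})

test_that("the published variance percentages are internally consistent with the Phi statistics", {
  # with among-group and among-colony-within-group percentages a and b,
  # Phi_ST = (a + b)/100 and Phi_SC = b/(100 - a)
  a <- 14.87; b <- 12.11
  expect_equal((a + b) / 100, 0.2698, tolerance = 5e-4)
  expect_equal(b / (100 - a), 0.1422, tolerance = 5e-4)
})

test_that("locus-by-locus SNP AMOVA matches oracles and allows negative components", {
  # single SNP fixed between the two islands, two colonies each
  g <- matrix(c(0L, 0L, 0L, 0L, 2L, 2L, 2L, 2L), ncol = 1)
  gm <- toy_genotypes(g, c("CHA", "CHA", "CHB", "CHB",
                           "AZA", "AZA", "AZB", "AZB"))
  groups <- c(CHA = "CHR", CHB = "CHR", AZA = "AZR", AZB = "AZR")
  am <- amova_snp(gm, groups, n_permutations = 0)
  expect_equal(am$phi[["phi_st"]], 1)

  # toy 3-locus matrix vs locus-by-locus direct enumeration
  set.seed(10)
  g <- matrix(sample(c(0L, 1L, 2L), 36, TRUE), nrow = 12)
  gm <- toy_genotypes(g, rep(c("CHA", "CHB", "AZA", "AZB"), each = 3))
  am <- amova_snp(gm, groups, n_permutations = 0)
  pop <- rep(1:4, each = 3)
  comp <- c(0, 0, 0)
  for (l in 1:3) {
    d2 <- outer(g[, l], g[, l], function(x, y) (x - y)^2)
    o <- oracle_amova3(d2, pop, c(1, 1, 2, 2))
    comp <- comp + o$sigma2
  }
  expect_equal(unname(am$sigma2), comp, tolerance = 1e-9)
  expect_equal(am$phi[["phi_st"]], (comp[1] + comp[2]) / sum(comp),
               tolerance = 1e-9)

  # negative within-group among-colony components are legal output
  set.seed(11)
  found_negative <- FALSE
  for (s in 1:20) {
    g <- matrix(sample(c(0L, 1L, 2L), 120, TRUE), nrow = 12)
    am <- amova_snp(toy_genotypes(g, rep(c("CHA", "CHB", "AZA", "AZB"),
                                         each = 3)),
                    groups, n_permutations = 0)
    if (any(am$sigma2 < 0)) found_negative <- TRUE
  }
  expect_true(found_negative)
})

test_that("Benjamini-Yekutieli matches hand arithmetic and dominates BH", {
  # m = 3, c(3) = 1 + 1/2 + 1/3
  expect_equal(benjamini_yekutieli(c(0.001, 0.02, 0.2)),
               c(0.0055, 0.055, 0.3666667), tolerance = 1e-6)
  expect_equal(benjamini_yekutieli(rep(0, 4)), rep(0, 4))
  expect_equal(benjamini_yekutieli(0.037), 0.037)  # m = 1 identity
  expect_error(benjamini_yekutieli(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(12)
  p <- runif(50)
  by <- benjamini_yekutieli(p)
  bh <- stats::p.adjust(p, "BH")
  expect_true(all(by >= bh - 1e-12))
  expect_true(all(bh >= p - 1e-12))
  # order preservation (monotone in the raw p-values; adjusted values may tie)
  expect_true(all(diff(by[order(p)]) >= -1e-12))
})

test_that("windowed Weir-Cockerham Fst behaves at its limits and matches the oracle", {
  # identical allele frequencies by construction: mean ~ 0
  g <- rbind(matrix(rep(c(0L, 1L, 2L, 1L), 25), nrow = 1)[rep(1, 6), ],
             matrix(rep(c(0L, 1L, 2L, 1L), 25), nrow = 1)[rep(1, 6), ])
  gm <- toy_genotypes(g, rep(c("x", "y"), each = 6))
  wf <- windowed_fst(gm, n_windows = 4)
  expect_lt(abs(wf$mean), 1e-9)

  # all SNPs fixed different: mean 1, sd 0
  g <- rbind(matrix(0L, 6, 40), matrix(2L, 6, 40))
  gm <- toy_genotypes(g, rep(c("x", "y"), each = 6))
  wf <- windowed_fst(gm, n_windows = 5)
  expect_equal(wf$mean, 1)
  expect_equal(wf$sd, 0)

  expect_error(windowed_fst(gm, n_windows = 100), "fewer SNPs")

  # multi-locus estimator equals the per-SNP component oracle ratio
  set.seed(14)
  g <- matrix(sample(c(0L, 1L, 2L, NA), 240, TRUE, prob = c(.4, .3, .2, .1)),
              nrow = 12)
  keep <- apply(g, 2, function(col) {
    s <- sum(col, na.rm = TRUE); n <- sum(!is.na(col))
    s > 0 && s < 2 * n && all(tapply(!is.na(col), rep(c("x", "y"), each = 6), sum) > 0)
  })
  g <- g[, keep, drop = FALSE]
  gm <- toy_genotypes(g, rep(c("x", "y"), each = 6))
  comp <- t(vapply(seq_len(ncol(g)), function(s)
    oracle_wc_single(g[, s], rep(c("x", "y"), each = 6)), numeric(3)))
  expect_equal(wc_fst(gm), sum(comp[, "a"]) / sum(comp), tolerance = 1e-9)
})

test_that("island-model simulation recovers the drift-migration balance scale", {
  # symmetric two-deme island model: moderate Fst, compared against the
  # same data's oracle estimator (independent code path), not a constant
  cfg <- coalescent_config(c(12, 12), N = c(1000, 1000),
                           M = matrix(c(0, 2.5e-4, 2.5e-4, 0), 2),
                           T0 = 4e4, mu = 2e-6, n_loci = 4000, seed = 19)
  gm <- simulate_snp_panel(cfg)
  pop <- gm$population
  comp <- t(vapply(seq_len(ncol(gm$geno)), function(s)
    oracle_wc_single(gm$geno[, s], pop), numeric(3)))
  ok <- stats::complete.cases(comp)
  expect_equal(wc_fst(gm), sum(comp[ok, "a"]) / sum(comp[ok, ]),
               tolerance = 1e-9)
})
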