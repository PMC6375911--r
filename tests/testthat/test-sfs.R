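# Folded joint spectrum construction, projection, folding rules, bootstrap
# and the text format.

test_that("direct counting, dimensions and mass conservation", {
  # one SNP: pop1 carries 1 of 6 alleles, pop2 0 of 4 -> cell (1, 0)
  g <- cbind(c(1L, 0L, 0L, 0L, 0L))
  gm <- toy_genotypes(g, c("p1", "p1", "p1", "p2", "p2"))
  sfs <- folded_2dsfs(gm, "p1", "p2")
  expect_equal(sfs$n1, 6L)
  expect_equal(sfs$n2, 4L)
  expect_equal(sfs$counts[2, 1], 1)
  expect_equal(sum(sfs$counts), 1)

  # empty SNP set: all-zero spectrum
  gm0 <- toy_genotypes(matrix(integer(0), 5, 0), c("p1", "p1", "p1", "p2", "p2"))
  sfs0 <- folded_2dsfs(gm0, "p1", "p2", n1 = 6, n2 = 4)
  expect_true(all(sfs0$counts == 0))
  expect_equal(sfs0$n_snps_used, 0)

  # the empirical panel shape: 11 + 10 diploids, no missingness -> 23 x 21
  set.seed(2)
  g <- matrix(sample(c(0L, 1L, 2L), 21 * 50, TRUE), nrow = 21)
  gm <- toy_genotypes(g, rep(c("CHR", "AZR"), c(11, 10)))
  sfs <- folded_2dsfs(gm, "CHR", "AZR")
  expect_equal(dim(sfs$counts), c(23L, 21L))
  expect_equal(sum(sfs$counts), sfs$n_snps_used)
  # masked cells carry no mass
  expect_true(all(sfs$counts[sfs$mask] == 0))
})

test_that("projection equals direct counting at full size and absorbs missingness", {
  set.seed(21)
  g <- matrix(sample(c(0L, 1L, 2L), 10 * 200, TRUE, prob = c(.6, .3, .1)),
              nrow = 10)
  pops <- rep(c("a", "b"), each = 5)
  gm <- toy_genotypes(g, pops)
  sfs <- folded_2dsfs(gm, "a", "b")         # full projection (no missingness)
  # direct counting oracle with the same fold rule
  n1 <- 10; n2 <- 10
  acc <- matrix(0, n1 + 1, n2 + 1)
  for (s in seq_len(ncol(g))) {
    d1 <- sum(g[1:5, s]); d2 <- sum(g[6:10, s])
    t <- d1 + d2
    if (t < 10) acc[d1 + 1, d2 + 1] <- acc[d1 + 1, d2 + 1] + 1
    else if (t > 10) acc[n1 - d1 + 1, n2 - d2 + 1] <- acc[n1 - d1 + 1, n2 - d2 + 1] + 1
    else if (d1 == n1 - d1 && d2 == n2 - d2) acc[d1 + 1, d2 + 1] <- acc[d1 + 1, d2 + 1] + 1
    else {
      acc[d1 + 1, d2 + 1] <- acc[d1 + 1, d2 + 1] + 0.5
      acc[n1 - d1 + 1, n2 - d2 + 1] <- acc[n1 - d1 + 1, n2 - d2 + 1] + 0.5
    }
  }
  expect_equal(sfs$counts, acc, tolerance = 1e-12)

  # "lower" tie rule puts whole SNPs on the lexicographically smaller cell
  sfs_l <- folded_2dsfs(gm, "a", "b", tie = "lower")
  expect_equal(sum(sfs_l$counts), sum(sfs$counts))
  expect_true(all(abs(sfs_l$counts - round(sfs_l$counts)) < 1e-12))

  # with missing data, mass is still conserved per usable SNP
  gmiss <- g
  set.seed(22)
  gmiss[sample(length(g), 150)] <- NA
  gmm <- toy_genotypes(gmiss, pops)
  sfs_m <- folded_2dsfs(gmm, "a", "b", n1 = 6, n2 = 6)
  expect_equal(sum(sfs_m$counts), sfs_m$n_snps_used, tolerance = 1e-9)
  expect_lte(sfs_m$n_snps_used, ncol(g))
})

test_that("folding a folded spectrum is the identity", {
  set.seed(23)
  m <- matrix(runif(9 * 7), 9, 7)
  f1 <- petrelpop:::fold_2d(m, "half")
  f2 <- petrelpop:::fold_2d(f1, "half")
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("locus block bootstrap preserves structure and determinism", {
  set.seed(24)
  g <- matrix(sample(c(0L, 1L, 2L), 8 * 120, TRUE), nrow = 8)
  gm <- toy_genotypes(g, rep(c("a", "b"), each = 4),
                      locus_id = rep(paste0("L", 1:40), each = 3))
  expect_length(bootstrap_sfs(gm, 0, seed = 1), 0)

  reps <- bootstrap_sfs(gm, 40, seed = 9)
  tot <- vapply(reps, function(x) sum(x$counts), numeric(1))
  # mean replicate SNP mass close to the original count
  expect_lt(abs(mean(tot) - 120) / 120, 0.1)
  # deterministic given seed
  reps2 <- bootstrap_sfs(gm, 40, seed = 9)
  expect_identical(lapply(reps, `[[`, "counts"), lapply(reps2, `[[`, "counts"))

  # single-locus input: every replicate equals the original
  gm1 <- toy_genotypes(g[, 1:3], rep(c("a", "b"), each = 4),
                       locus_id = rep("L1", 3))
  r1 <- bootstrap_sfs(gm1, 5, seed = 2)
  ref <- folded_2dsfs(gm1, "a", "b")
  for (x in r1) expect_equal(x$counts, ref$counts)
})

test_that("the SFS text format round-trips", {
  tmp <- withr::local_tempdir()
  set.seed(25)
  g <- matrix(sample(c(0L, 1L, 2L), 6 * 60, TRUE), nrow = 6)
  gm <- toy_genotypes(g, rep(c("a", "b"), each = 3))
  sfs <- folded_2dsfs(gm, "a", "b")
  p <- file.path(tmp, "x.sfs")
  write_sfs(sfs, p)
  expect_match(readLines(p, n = 1), "^6 6 folded$")
  rt <- read_sfs(p)
  expect_equal(rt$counts, sfs$counts, tolerance = 1e-9)
  expect_equal(rt$n1, sfs$n1)
  expect_equal(rt$n2, sfs$n2)
})
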