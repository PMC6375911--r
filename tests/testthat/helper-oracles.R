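# Independent oracles and small fixture builders used across the suite.
# Every oracle is a direct transcription of the defining formulas, computed
# by plain enumeration, kept free of the package's own code paths.

options(petrelpop.verbose = FALSE)

# build a tiny alignment from literal sequences
toy_alignment <- function(seqs, colony, group = colony,
                          ids = paste0("s", seq_along(seqs))) {
  hap_alignment(ids, seqs, colony, group)
}

# Hamming distance between two sequences over jointly unambiguous sites
oracle_hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  ok <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  sum(av[ok] != bv[ok])
}

# Tajima's D from S, K and n by a literal transcription of the constants
oracle_tajima_d <- function(S, K, n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (K - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Two-level AMOVA by direct sums-of-squares enumeration over individuals.
# d2: squared-distance matrix; pop: integer labels.
oracle_amova2 <- function(d2, pop) {
  N <- nrow(d2)
  pops <- unique(pop)
  P <- length(pops)
  ss_set <- function(idx) {
    if (length(idx) < 2) return(0)
    s <- 0
    for (i in idx) for (j in idx) s <- s + d2[i, j]
    s / (2 * length(idx))
  }
  ss_tot <- ss_set(seq_len(N))
  ssd_wp <- sum(vapply(pops, function(p) ss_set(which(pop == p)), 0))
  ssd_ap <- ss_tot - ssd_wp
  n_p <- vapply(pops, function(p) sum(pop == p), 0)
  nc <- (N - sum(n_p^2) / N) / (P - 1)
  s2w <- ssd_wp / (N - P)
  s2a <- (ssd_ap / (P - 1) - s2w) / nc
  list(sigma2 = c(among = s2a, within = s2w),
       phi_st = s2a / (s2a + s2w))
}

# Three-level AMOVA by direct enumeration: pop per individual, grp per pop.
oracle_amova3 <- function(d2, pop, grp_of_pop) {
  N <- nrow(d2)
  pops <- sort(unique(pop))
  P <- length(pops)
  grp <- grp_of_pop[pop]
  grps <- sort(unique(grp_of_pop))
  G <- length(grps)
  ss_set <- function(idx) {
    if (length(idx) < 2) return(0)
    s <- 0
    for (i in idx) for (j in idx) s <- s + d2[i, j]
    s / (2 * length(idx))
  }
  ss_tot <- ss_set(seq_len(N))
  ss_pop <- sum(vapply(pops, function(p) ss_set(which(pop == p)), 0))
  ss_grp <- sum(vapply(grps, function(g) ss_set(which(grp == g)), 0))
  ssd_wp <- ss_pop
  ssd_ap <- ss_grp - ss_pop
  ssd_ag <- ss_tot - ss_grp
  n_p <- vapply(pops, function(p) sum(pop == p), 0)
  n_g <- vapply(grps, function(g) sum(grp == g), 0)
  A <- sum(vapply(grps, function(g)
    sum(n_p[grp_of_pop[pops] == g]^2) / n_g[grps == g], 0))
  B <- sum(n_p^2) / N
  C <- sum(n_g^2) / N
  np1 <- (N - A) / (P - G)
  np2 <- (A - B) / (G - 1)
  np3 <- (N - C) / (G - 1)
  s2c <- ssd_wp / (N - P)
  s2b <- (ssd_ap / (P - G) - s2c) / np1
  s2a <- (ssd_ag / (G - 1) - s2c - np2 * s2b) / np3
  tot <- s2a + s2b + s2c
  list(sigma2 = c(s2a, s2b, s2c),
       phi_st = (s2a + s2b) / tot,
       phi_sc = s2b / (s2b + s2c),
       phi_ct = s2a / tot)
}

# Weir-Cockerham (1984) theta for one biallelic SNP, literal transcription
oracle_wc_single <- function(geno, pop) {
  pops <- unique(pop)
  r <- length(pops)
  n_i <- vapply(pops, function(p) sum(!is.na(geno[pop == p])), 0)
  p_i <- vapply(pops, function(p) sum(geno[pop == p], na.rm = TRUE), 0) / (2 * n_i)
  h_i <- vapply(pops, function(p) mean(geno[pop == p] == 1, na.rm = TRUE), 0)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# toy genotype matrix builder (no minor-allele recoding)
toy_genotypes <- function(geno, population, locus_id = NULL) {
  geno <- as.matrix(geno)
  if (is.null(locus_id))
    locus_id <- if (ncol(geno) == 0) character(0) else
      paste0("L", seq_len(ncol(geno)))
  genotype_matrix(paste0("i", seq_len(nrow(geno))), population, geno,
                  locus_id, recode_minor = FALSE)
}

# analytic folded single-population SFS shape (constant size):
# eta_i proportional to (1/i + 1/(n-i)) / (1 + delta_{i, n-i})
oracle_folded_1d <- function(n) {
  i <- seq_len(floor(n / 2))
  w <- (1 / i + 1 / (n - i)) / (1 + as.numeric(i == n - i))
  w / sum(w)
}
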