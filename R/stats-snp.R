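# SNP-panel statistics: Tajima's D and nucleotide diversity scaled to total
# sequenced sites, locus-by-locus hierarchical AMOVA, and windowed
# Weir-Cockerham Fst.

#' Tajima's D and nucleotide diversity from a SNP genotype matrix
#'
#' Per-site complete-case: at each SNP the haploid sample size is twice the
#' number of individuals with calls. Nucleotide diversity sums the unbiased
#' per-site heterozygosity `n/(n-1) * 2p(1-p)` over SNPs and divides by
#' `total_sites` (the number of sequenced sites, polymorphic or not, e.g.
#' loci x locus length). Tajima's D uses the summed pairwise diversity and
#' the SNP count with constants evaluated at the (rounded) mean haploid
#' sample size across sites.
#'
#' @param gm a [genotype_matrix()].
#' @param total_sites total number of sequenced sites the SNPs were called
#'   from; required to scale diversity per site.
#' @return list with `S`, `pi`, `K`, `D`, `n_haploid` (mean haploid calls).
#' @export
snp_summary <- function(gm, total_sites) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (missing(total_sites) || is.null(total_sites))
    stop("total_sites is required to scale diversity per site")
  g <- gm$geno
  n_call <- colSums(!is.na(g))
  keep <- n_call >= 2
  g <- g[, keep, drop = FALSE]
  n_call <- n_call[keep]
  nh <- 2 * n_call
  cnt <- colSums(g, na.rm = TRUE)
  p <- cnt / nh
  poly <- p > 0 & p < 1
  S <- sum(poly)
  if (S == 0)
    return(list(S = 0L, pi = 0, K = 0, D = NaN, n_haploid = mean(nh)))
  het <- (nh / (nh - 1) * 2 * p * (1 - p))[poly]
  K <- sum(het) # mean pairwise differences, summed over SNPs
  nbar <- round(mean(nh[poly]))
  list(S = as.integer(S), pi = K / total_sites, K = K,
       D = tajima_d_from_sk(S, K, nbar), n_haploid = mean(nh))
}

#' Tajima's D from SNP genotypes
#'
#' @inheritParams snp_summary
#' @return numeric scalar (NaN when no site is polymorphic).
#' @export
tajimas_d_snp <- function(gm, total_sites) {
  snp_summary(gm, total_sites)$D
}

#' Locus-by-locus hierarchical AMOVA for SNP genotypes
#'
#' Per-locus variance components are computed on complete cases (the
#' individuals called at that locus), using the squared allele-count
#' difference as distance, and summed over loci; the Phi statistics are
#' formed from the summed components. Permutation schemes are as in
#' [amova()], with the same permutation applied across loci.
#'
#' @param gm a [genotype_matrix()]; population labels are the colonies.
#' @param groups named map colony -> group.
#' @param n_permutations permutations per level (default 15000).
#' @param seed integer seed.
#' @return an object of class `amova_result` (no SSD table: components are
#'   sums over loci).
#' @export
amova_snp <- function(gm, groups, n_permutations = 15000, seed = 1) {
  stopifnot(inherits(gm, "genotype_matrix"))
  pops <- unique(gm$population)
  if (!all(pops %in% names(groups)))
    stop("groups must name every population: missing ",
         paste(setdiff(pops, names(groups)), collapse = ", "))
  grp_of_pop <- unname(groups[pops])
  grps <- unique(grp_of_pop)
  if (length(grps) < 2) stop("need at least two groups")
  geno <- gm$geno
  geno[is.na(geno)] <- -1L
  pop <- match(gm$population, pops) - 1L
  gop <- match(grp_of_pop, grps) - 1L
  if (n_permutations > 0) set.seed(derive_seed(seed, 0L))
  r <- cpp_amova_loci(geno, pop, gop, as.integer(n_permutations))
  sigma2 <- stats::setNames(r$sigma2,
                            c("among_groups", "among_colonies_within_groups",
                              "within_colonies"))
  structure(list(
    sigma2 = sigma2,
    percent = 100 * sigma2 / sum(sigma2),
    df = NULL, ssd = NULL,
    phi = stats::setNames(r$phi, c("phi_st", "phi_sc", "phi_ct")),
    p = stats::setNames(r$p, c("phi_st", "phi_sc", "phi_ct")),
    n_permutations = n_permutations, loci_used = r$loci_used),
    class = "amova_result")
}

# Weir & Cockerham (1984) per-SNP components a (among populations),
# b (among individuals within populations), c (within individuals).
#' @noRd
wc_components <- function(geno, pop) {
  pops <- unique(pop)
  r <- length(pops)
  n_i <- sapply(pops, function(p) colSums(!is.na(geno[pop == p, , drop = FALSE])))
  p_i <- sapply(pops, function(p)
    colSums(geno[pop == p, , drop = FALSE], na.rm = TRUE)) / (2 * n_i)
  h_i <- sapply(pops, function(p)
    colMeans(geno[pop == p, , drop = FALSE] == 1L, na.rm = TRUE))
  if (is.null(dim(n_i))) {
    n_i <- matrix(n_i, nrow = 1); p_i <- matrix(p_i, nrow = 1)
    h_i <- matrix(h_i, nrow = 1)
  }
  nbar <- rowMeans(n_i)
  nc <- (r * nbar - rowSums(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- rowSums(n_i * p_i) / (r * nbar)
  s2 <- rowSums(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n_i * h_i) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  cbind(a = a, b = b, c = cc)
}

#' Multi-locus Weir-Cockerham Fst
#'
#' @param gm a [genotype_matrix()] with two or more populations.
#' @param snps optional SNP index subset.
#' @return the ratio-of-sums estimator `sum(a) / sum(a + b + c)`.
#' @export
wc_fst <- function(gm, snps = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (length(unique(gm$population)) < 2) stop("need at least two populations")
  geno <- gm$geno
  if (!is.null(snps)) geno <- geno[, snps, drop = FALSE]
  comp <- wc_components(geno, gm$population)
  ok <- stats::complete.cases(comp)
  sum(comp[ok, "a"]) / sum(comp[ok, ])
}

#' Windowed Weir-Cockerham Fst
#'
#' SNPs are partitioned, in input order, into `n_windows` near-equal blocks
#' (RAD loci are unordered, so windows are SNP-count blocks, not genomic
#' intervals); the multi-locus estimator is computed per window and its mean
#' and standard deviation across windows are reported.
#'
#' @param gm a [genotype_matrix()].
#' @param n_windows number of windows (default 500).
#' @return list with `mean`, `sd`, `per_window`.
#' @export
windowed_fst <- function(gm, n_windows = 500) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n_snp <- ncol(gm$geno)
  if (n_windows < 1) stop("n_windows must be >= 1")
  if (n_snp < n_windows) stop("fewer SNPs (", n_snp, ") than windows (",
                              n_windows, ")")
  win <- cut(seq_len(n_snp), n_windows, labels = FALSE)
  fst <- vapply(seq_len(n_windows), function(w) wc_fst(gm, which(win == w)),
                numeric(1))
  list(mean = mean(fst), sd = stats::sd(fst), per_window = fst)
}

#' Benjamini-Yekutieli FDR correction
#'
#' Adjusted p-values controlling the false discovery rate under arbitrary
#' dependence: `p_i` is adjusted by `m * c(m) / rank`, with
#' `c(m) = sum_{k=1}^m 1/k`, enforced monotone and clipped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, in the input order.
#' @export
benjamini_yekutieli <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BY")
}
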