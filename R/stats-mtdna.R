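# Haplotype summary statistics, pairwise Phi_ST and hierarchical AMOVA.

# integer-code an alignment; ambiguous states (N, -) become NA
#' @noRd
aln_codes <- function(aln) {
  m <- matrix(match(aln$seq, c("A", "C", "G", "T")), nrow = nrow(aln$seq))
  rownames(m) <- aln$ids
  m
}

#' Pairwise nucleotide-difference (Hamming) matrix
#'
#' Counts, for every pair of sequences, the number of differing sites among
#' the sites where both members of the pair carry an unambiguous base
#' (pairwise deletion; global trimming is available in
#' [read_fasta_alignment()]).
#'
#' @param aln a [hap_alignment()].
#' @return symmetric integer matrix of counts with sample ids as dimnames.
#' @export
pairwise_differences <- function(aln) {
  stopifnot(inherits(aln, "hap_alignment"))
  n <- length(aln$ids)
  if (n == 0) stop("empty alignment")
  cd <- aln_codes(aln)
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1)) {
    a <- cd[i, ]
    for (j in (i + 1):n) {
      b <- cd[j, ]
      ok <- !is.na(a) & !is.na(b)
      d[i, j] <- d[j, i] <- sum(a[ok] != b[ok])
    }
  }
  d
}

#' @noRd
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' @noRd
tajima_d_from_sk <- function(S, K, n) {
  if (S == 0 || n < 4) return(NaN)
  cc <- tajima_constants(n)
  (K - S / cc$a1) / sqrt(cc$e1 * S + cc$e2 * S * (S - 1))
}

#' Haplotype summary statistics
#'
#' Computes, for an alignment (or a per-colony subset obtained with
#' [subset_colonies()]): unbiased haplotype diversity
#' `H = n/(n-1) (1 - sum p_h^2)`, mean pairwise differences `K`, nucleotide
#' diversity per site `pi = K / L`, the number of segregating sites `S`, and
#' Tajima's D from `S` and `K`. `D` is `NaN` when `S = 0`.
#'
#' @param aln a [hap_alignment()] with at least two samples.
#' @return an object of class `summary_stats`, a list with `H`, `pi`, `K`,
#'   `S`, `D`, `n`, `L`.
#' @export
summary_stats <- function(aln) {
  stopifnot(inherits(aln, "hap_alignment"))
  n <- length(aln$ids)
  if (n < 2) stop("need at least two sequences")
  L <- ncol(aln$seq)
  cd <- aln_codes(aln)
  seg <- apply(cd, 2, function(col) length(unique(col[!is.na(col)])) > 1)
  S <- sum(seg)
  d <- pairwise_differences(aln)
  K <- mean(d[upper.tri(d)])
  hap <- apply(aln$seq, 1, paste0, collapse = "")
  p <- table(hap) / n
  H <- n / (n - 1) * (1 - sum(p^2))
  structure(list(H = H, pi = K / L, K = K, S = as.integer(S),
                 D = tajima_d_from_sk(S, K, n), n = n, L = L,
                 n_haplotypes = length(p)),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("n = %d, L = %d sites: H = %.3f, pi = %.5f, K = %.3f, S = %d, Tajima's D = %.3f\n",
              x$n, x$L, x$H, x$pi, x$K, x$S, x$D))
  invisible(x)
}

# choose the squared distance entering AMOVA from a difference-count matrix
#' @noRd
amova_d2 <- function(dmat, distance) {
  switch(distance,
         pairwise_difference = dmat,
         squared_pairwise_difference = dmat^2,
         stop("unknown distance: ", distance))
}

#' Pairwise Phi_ST between two populations of an alignment
#'
#' Two-level AMOVA on the pairwise-difference distances between the samples
#' of two colonies; `Phi_ST = sigma2_among / sigma2_total`, with a
#' permutation test shuffling individuals between the two colonies.
#'
#' @param aln a [hap_alignment()].
#' @param popA,popB colony labels, each with at least two samples.
#' @param n_permutations permutations for the significance test (default
#'   10000; 0 skips the test).
#' @param seed integer seed for the permutations.
#' @param distance `"pairwise_difference"` (default; the difference count is
#'   used as the squared distance, as in haplotypic AMOVA with
#'   pairwise-difference distances) or `"squared_pairwise_difference"`.
#' @return list with `phi_st`, `p`, `sigma2` (among, within).
#' @export
phi_st <- function(aln, popA, popB, n_permutations = 10000, seed = 1,
                   distance = c("pairwise_difference",
                                "squared_pairwise_difference")) {
  distance <- match.arg(distance)
  stopifnot(inherits(aln, "hap_alignment"))
  for (p in c(popA, popB))
    if (sum(aln$colony == p) < 2)
      stop("population '", p, "' absent or with fewer than two samples")
  sub <- subset_colonies(aln, c(popA, popB))
  d2 <- amova_d2(pairwise_differences(sub), distance)
  pop <- as.integer(sub$colony == popB)
  if (n_permutations > 0) set.seed(derive_seed(seed, 0L))
  r <- cpp_amova2(d2, pop, as.integer(n_permutations))
  list(phi_st = r$phi_st, p = if (n_permutations > 0) r$p else NA_real_,
       sigma2 = stats::setNames(r$sigma2, c("among", "within")))
}

#' Hierarchical (three-level) AMOVA with permutation tests
#'
#' Partitions the molecular variance of squared inter-individual distances
#' into among-group, among-colony-within-group and within-colony components
#' and reports the Phi statistics with permutation p-values: individuals
#' among all colonies (Phi_ST), individuals among colonies within groups
#' (Phi_SC) and whole colonies among groups (Phi_CT); tie-tolerant p-values
#' `(#{perm >= obs} + 1)/(B + 1)`. Negative variance components are
#' retained, not truncated.
#'
#' @param aln a [hap_alignment()] carrying colony and group labels.
#' @param n_permutations permutations per level (default 15000).
#' @param seed integer seed.
#' @param distance see [phi_st()].
#' @return an object of class `amova_result` with the components table
#'   (`sigma2`, `df`, `ssd`, `percent`), `phi` (ST, SC, CT), `p` and
#'   `n_permutations`.
#' @export
amova <- function(aln, n_permutations = 15000, seed = 1,
                  distance = c("pairwise_difference",
                               "squared_pairwise_difference")) {
  distance <- match.arg(distance)
  stopifnot(inherits(aln, "hap_alignment"))
  pops <- unique(aln$colony)
  grp_of_pop <- vapply(pops, function(p) aln$group[aln$colony == p][1],
                       character(1))
  groups <- unique(grp_of_pop)
  if (length(groups) < 2) stop("need at least two groups")
  sizes <- table(aln$colony)
  if (any(sizes == 1))
    pp_log("colony with a single member: ",
           paste(names(sizes)[sizes == 1], collapse = ", "))
  d2 <- amova_d2(pairwise_differences(aln), distance)
  pop <- match(aln$colony, pops) - 1L
  gop <- match(grp_of_pop, groups) - 1L
  if (n_permutations > 0) set.seed(derive_seed(seed, 0L))
  r <- cpp_amova3(d2, pop, gop, as.integer(n_permutations))
  sigma2 <- stats::setNames(r$sigma2,
                            c("among_groups", "among_colonies_within_groups",
                              "within_colonies"))
  structure(list(
    sigma2 = sigma2,
    percent = 100 * sigma2 / sum(sigma2),
    df = stats::setNames(r$df, names(sigma2)),
    ssd = stats::setNames(r$ssd, names(sigma2)),
    phi = stats::setNames(r$phi, c("phi_st", "phi_sc", "phi_ct")),
    p = stats::setNames(r$p, c("phi_st", "phi_sc", "phi_ct")),
    n_permutations = n_permutations),
    class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("Hierarchical AMOVA (", x$n_permutations, " permutations)\n", sep = "")
  tab <- if (is.null(x$df)) {
    data.frame(sigma2 = x$sigma2, percent = x$percent)
  } else {
    data.frame(df = x$df, SSD = x$ssd, sigma2 = x$sigma2,
               percent = x$percent)
  }
  print(round(tab, 4))
  cat(sprintf("Phi_ST = %.4f (p = %.4g), Phi_SC = %.4f (p = %.4g), Phi_CT = %.4f (p = %.4g)\n",
              x$phi[1], x$p[1], x$phi[2], x$p[2], x$phi[3], x$p[3]))
  invisible(x)
}

#' Pairwise Phi_ST matrix across all colonies
#'
#' Lower triangle: Phi_ST; upper triangle: raw permutation p-values.
#' Benjamini-Yekutieli adjusted p-values for the whole set of comparisons
#' are attached.
#'
#' @inheritParams amova
#' @param n_permutations permutations per pairwise test (default 10000).
#' @return an object of class `phi_st_matrix`: list with `matrix` (Phi
#'   below, raw p above the diagonal), `p_adjusted` (BY) and `pairs`.
#' @export
phi_st_matrix <- function(aln, n_permutations = 10000, seed = 1,
                          distance = c("pairwise_difference",
                                       "squared_pairwise_difference")) {
  distance <- match.arg(distance)
  pops <- unique(aln$colony)
  k <- length(pops)
  m <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  pairs <- data.frame(popA = character(0), popB = character(0),
                      phi_st = numeric(0), p = numeric(0))
  idx <- 0L
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      idx <- idx + 1L
      r <- phi_st(aln, pops[i], pops[j], n_permutations,
                  seed = derive_seed(seed, idx), distance = distance)
      m[j, i] <- r$phi_st
      m[i, j] <- r$p
      pairs <- rbind(pairs, data.frame(popA = pops[i], popB = pops[j],
                                       phi_st = r$phi_st, p = r$p))
    }
  }
  pairs$p_adjusted <- benjamini_yekutieli(pairs$p)
  structure(list(matrix = m, pairs = pairs), class = "phi_st_matrix")
}

#' @export
print.phi_st_matrix <- function(x, ...) {
  cat("Pairwise Phi_ST (lower triangle) / raw permutation p (upper triangle)\n")
  print(round(x$matrix, 4))
  invisible(x)
}
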