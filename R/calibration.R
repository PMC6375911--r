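# Rate and size scaling arithmetic: per-generation mutation rate, Poisson
# locus-class substitution rates and their weighted average, Theta/M
# conversion to effective sizes and migrant numbers, and allele-dropout
# haplotype subsampling.

#' Per-generation mutation rate from a per-Myr substitution rate
#'
#' `mu = rate_per_myr * generation_time / 1e6`, exactly linear in both
#' arguments.
#'
#' @param rate_per_myr substitutions per site per million years (> 0).
#' @param generation_time_years generation time in years (> 0).
#' @return mutation rate in substitutions per site per generation.
#' @export
per_generation_rate <- function(rate_per_myr, generation_time_years) {
  if (any(rate_per_myr <= 0) || any(generation_time_years <= 0))
    stop("rate and generation time must be positive")
  rate_per_myr * generation_time_years / 1e6
}

#' Fit a Poisson model to per-locus SNP counts
#'
#' The number of polymorphic sites per neutrally evolving locus is expected
#' to be Poisson; `lambda` is estimated by the sample mean and a chi-squared
#' goodness-of-fit test is run on count classes with tail classes pooled so
#' that each expected count is at least 5 (one degree of freedom spent on
#' the estimated mean).
#'
#' @param counts nonnegative integer SNP counts, one per locus.
#' @return list with `lambda`, `chisq`, `df`, `p_value`, and the class
#'   table used.
#' @export
fit_poisson_snp_counts <- function(counts) {
  if (length(counts) == 0) stop("empty input")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  lambda <- mean(counts)
  if (lambda == 0)
    return(list(lambda = 0, chisq = NA_real_, df = NA_integer_,
                p_value = NA_real_, classes = NULL))
  n <- length(counts)
  kmax <- max(counts)
  obs <- tabulate(counts + 1L, nbins = kmax + 1L)
  expd <- n * stats::dpois(0:kmax, lambda)
  expd[kmax + 1L] <- expd[kmax + 1L] + n * (1 - stats::ppois(kmax, lambda))
  # pool upper tail classes until each expected count >= 5
  while (length(expd) > 2 && expd[length(expd)] < 5) {
    k <- length(expd)
    expd[k - 1] <- expd[k - 1] + expd[k]
    obs[k - 1] <- obs[k - 1] + obs[k]
    expd <- expd[-k]; obs <- obs[-k]
  }
  chisq <- sum((obs - expd)^2 / expd)
  df <- max(1L, length(obs) - 2L)
  list(lambda = lambda, chisq = chisq, df = df,
       p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
       classes = data.frame(count = seq_along(obs) - 1L, observed = obs,
                            expected = expd))
}

#' Substitution rate for a locus class with S SNPs
#'
#' Loci with `S` polymorphic sites evolve at the class rate
#' `mu_S = S * mu / lambda` (i.e. `S / (lambda / mu)`), where `lambda` is
#' the Poisson mean SNP count per locus and `mu` the background rate.
#'
#' @param S SNP count of the class (>= 0); vectorized.
#' @param lambda Poisson mean SNPs per locus (> 0).
#' @param mu background mutation rate per site per generation.
#' @return class rate(s) `mu_S`.
#' @export
class_rate <- function(S, lambda, mu) {
  if (lambda <= 0) stop("lambda must be positive")
  if (any(S < 0)) stop("S must be nonnegative")
  S * mu / lambda
}

#' Weighted average of class rates
#'
#' @param rates class rates (e.g. from [class_rate()]).
#' @param weights nonnegative weights (e.g. observed locus counts per
#'   class, or truncated Poisson masses); need not sum to one.
#' @return the weighted average rate.
#' @export
weighted_average <- function(rates, weights) {
  if (length(rates) != length(weights)) stop("rates and weights differ in length")
  if (any(weights < 0) || sum(weights) <= 0) stop("invalid weights")
  sum(rates * weights) / sum(weights)
}

#' Scale a mutation-scaled population size to an effective size
#'
#' `Ne = Theta / (ploidy_factor * mu)`; the default factor 4 is the diploid
#' nuclear convention `Theta = 4 Ne mu` per site.
#'
#' @param theta mutation-scaled size (> 0).
#' @param mu mutation rate per site per generation (> 0).
#' @param ploidy_factor 4 for diploid nuclear loci (default), 2 for haploid.
#' @return effective population size.
#' @export
scale_theta <- function(theta, mu, ploidy_factor = 4) {
  if (any(theta <= 0) || any(mu <= 0)) stop("theta and mu must be positive")
  theta / (ploidy_factor * mu)
}

#' Scale mutation-scaled migration to migrants per generation
#'
#' With `Theta = 4 Ne mu` and the mutation-scaled immigration rate
#' `M = m / mu`, the number of effective migrants per generation is
#' `Nm = Theta * M / 4`.
#'
#' @param theta mutation-scaled size of the receiving population.
#' @param M mutation-scaled immigration rate.
#' @param ploidy_factor as in [scale_theta()].
#' @return migrants per generation `Nm`.
#' @export
scale_migrants <- function(theta, M, ploidy_factor = 4) {
  if (any(theta <= 0) || any(M < 0)) stop("invalid theta or M")
  theta * M / ploidy_factor
}

#' Randomly subsample one haplotype per individual per locus
#'
#' Allele-dropout correction for read-backed short-haplotype analyses: per
#' individual and locus a single allele is drawn uniformly, so heterozygote
#' miscalls due to dropout cannot bias the retained haplotype set.
#' Homozygotes are deterministic; missing genotypes stay missing.
#'
#' @param gm a [genotype_matrix()] with diploid codes.
#' @param seed integer seed (draws are reproducible).
#' @return a [genotype_matrix()] whose `geno` holds haploid allele codes in
#'   `{0, 1, NA}`; `attr(, "haploid")` is `TRUE`.
#' @export
subsample_haplotypes <- function(gm, seed) {
  stopifnot(inherits(gm, "genotype_matrix"))
  set.seed(derive_seed(seed, 0L))
  g <- gm$geno
  out <- g
  out[g == 2L] <- 1L
  het <- !is.na(g) & g == 1L
  out[het] <- rbinom(sum(het), 1L, 0.5)
  gm$geno <- out
  attr(gm, "haploid") <- TRUE
  gm
}
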