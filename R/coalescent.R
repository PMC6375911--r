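# Structured-coalescent configuration and genealogy simulation.
#
# The engine (src/coalescent.cpp) works backward in time with exponential
# waiting times. Sizes handed to the engine are haploid (pairwise
# coalescence rate k(k-1)/2 / size); the user-facing configuration takes
# diploid effective sizes for the nuclear SNP panel, and migration rates as
# backward per-lineage per-generation probabilities: `M[i, j]` is the rate
# at which a lineage currently in deme i traces its ancestry into deme j.

#' Two-deme coalescent configuration
#'
#' Describes the sampling scheme and piecewise-constant demography of a
#' two-deme (or single-deme) system: a recent epoch `[0, T1)`, an older
#' epoch `[T1, T0)`, and a merge of deme 2 into deme 1 at the divergence
#' time `T0` (all times in generations before present).
#'
#' @param sample_sizes haploid sample sizes per deme (length 1 or 2); for a
#'   diploid SNP panel of `k` individuals per deme use `2 * k`.
#' @param N diploid effective sizes per deme in the recent epoch.
#' @param M backward migration-rate matrix for the recent epoch (`M[i, j]` =
#'   per-generation probability that a lineage in deme i jumps to deme j);
#'   default zero.
#' @param N_ancient,M_ancient sizes and migration for the epoch `[T1, T0)`
#'   (default: same as recent; ignored when `T1` is `NULL`).
#' @param T0 divergence time in generations (finite unless migration keeps
#'   the demes connected); ignored for a single deme.
#' @param T1 optional regime-change time, `0 <= T1 <= T0`.
#' @param N_ancestral diploid size of the merged ancestral deme (default:
#'   oldest size of deme 1).
#' @param mu mutation rate, substitutions per site per generation.
#' @param locus_length locus length in bases (default 95, a RAD read).
#' @param n_loci number of independent loci to simulate.
#' @param seed mandatory integer seed for all stochastic use of the config.
#' @return an object of class `coalescent_config`.
#' @export
coalescent_config <- function(sample_sizes, N, M = NULL, N_ancient = NULL,
                              M_ancient = NULL, T0 = Inf, T1 = NULL,
                              N_ancestral = NULL, mu = 9.6e-9,
                              locus_length = 95, n_loci = 1000, seed) {
  D <- length(sample_sizes)
  if (!D %in% c(1L, 2L)) stop("sample_sizes must have length 1 or 2")
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (any(sample_sizes < 0) || sum(sample_sizes) < 2)
    stop("need nonnegative sample sizes totalling at least 2")
  if (length(N) != D || any(N <= 0)) stop("N must give a positive size per deme")
  if (is.null(M)) M <- matrix(0, D, D)
  M <- as.matrix(M)
  if (any(M < 0)) stop("migration rates must be nonnegative")
  diag(M) <- 0
  if (!is.null(T1)) {
    if (T1 < 0 || T1 > T0) stop("need 0 <= T1 <= T0")
    if (is.null(N_ancient)) N_ancient <- N
    if (is.null(M_ancient)) M_ancient <- M
    M_ancient <- as.matrix(M_ancient)
    diag(M_ancient) <- 0
    if (any(N_ancient <= 0)) stop("ancient sizes must be positive")
    if (any(M_ancient < 0)) stop("migration rates must be nonnegative")
  }
  if (D == 2 && !is.finite(T0)) {
    conn <- all(M[upper.tri(M) | lower.tri(M)] > 0) &&
      (is.null(T1) || all(M_ancient[upper.tri(M_ancient)] > 0,
                          M_ancient[lower.tri(M_ancient)] > 0))
    if (!conn)
      stop("with two demes, T0 must be finite unless migration connects both demes in all epochs")
  }
  if (is.null(N_ancestral))
    N_ancestral <- if (is.null(T1)) N[1] else N_ancient[1]
  structure(list(sample_sizes = as.integer(sample_sizes), N = N, M = M,
                 N_ancient = N_ancient, M_ancient = M_ancient, T0 = T0,
                 T1 = T1, N_ancestral = N_ancestral, mu = mu,
                 locus_length = locus_length, n_loci = as.integer(n_loci),
                 seed = as.integer(seed)),
            class = "coalescent_config")
}

# Translate a coalescent_config into the raw engine arguments.
#' @noRd
engine_args <- function(cfg) {
  D <- length(cfg$sample_sizes)
  zero <- matrix(0, D, D)
  etimes <- 0
  sizes <- matrix(2 * cfg$N, nrow = 1)
  migs <- list(cfg$M)
  if (!is.null(cfg$T1) && cfg$T1 > 0 && is.finite(cfg$T1)) {
    etimes <- c(etimes, cfg$T1)
    sizes <- rbind(sizes, 2 * cfg$N_ancient)
    migs <- c(migs, list(cfg$M_ancient))
  }
  merges <- matrix(numeric(0), 0, 3)
  if (D == 2 && is.finite(cfg$T0)) {
    merges <- matrix(c(cfg$T0, 1, 0), 1, 3) # deme 2 (0-based 1) into deme 1
    etimes <- c(etimes, cfg$T0)
    sizes <- rbind(sizes, c(2 * cfg$N_ancestral, 1))
    migs <- c(migs, list(zero))
  }
  list(samples = cfg$sample_sizes, etimes = etimes, sizes = sizes,
       migs = migs, merges = merges)
}

#' Simulate one genealogy under a coalescent configuration
#'
#' Continuous-time structured coalescent, backward in time; epochs switch at
#' `T1` and the demes merge at `T0`. Deterministic given `(seed,
#' locus_index)`.
#'
#' @param config a [coalescent_config()].
#' @param locus_index index of the locus (enters the derived seed).
#' @return an object of class `genealogy`: node times (generations), parent
#'   pointers (0 for the root), the deme in which each node was created, the
#'   per-lineage migration log, and `n_tips`.
#' @export
simulate_genealogy <- function(config, locus_index = 1L) {
  stopifnot(inherits(config, "coalescent_config"))
  ea <- engine_args(config)
  set.seed(derive_seed(config$seed, locus_index))
  g <- cpp_simulate_genealogy(ea$samples, ea$etimes, ea$sizes, ea$migs,
                              ea$merges)
  g$n_tips <- sum(config$sample_sizes)
  class(g) <- "genealogy"
  g
}

#' Total branch length of a genealogy, in lineage-generations
#' @param g a `genealogy`.
#' @return numeric scalar.
#' @export
total_branch_length <- function(g) {
  stopifnot(inherits(g, "genealogy"))
  has_parent <- g$parent > 0
  sum(g$time[g$parent[has_parent]] - g$time[has_parent])
}

#' Time to the most recent common ancestor of a genealogy
#' @param g a `genealogy`.
#' @return numeric scalar (generations).
#' @export
tmrca <- function(g) {
  stopifnot(inherits(g, "genealogy"))
  max(g$time)
}
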