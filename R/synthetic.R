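# Synthetic data generation: two-island diploid SNP panels (infinite sites)
# and multi-colony mtDNA alignments (finite sites, Jukes-Cantor).

#' Simulate a diploid SNP panel under a coalescent configuration
#'
#' Per locus one genealogy is simulated and mutations are dropped as
#' Poisson(mu x locus_length x total branch length) under the infinite-sites
#' model. Diploid individuals are formed by random pairing of haploid
#' lineages within demes (a fresh pairing per locus; loci are unlinked).
#' Only polymorphic sites are emitted. The generating configuration is
#' attached as `attr(, "truth")` for parameter-recovery tests.
#'
#' @param config a [coalescent_config()] with even haploid sample sizes.
#' @param deme_names population labels (default `"pop1"`, `"pop2"`).
#' @return a [genotype_matrix()] coded on the globally minor allele.
#' @export
simulate_snp_panel <- function(config, deme_names = NULL) {
  stopifnot(inherits(config, "coalescent_config"))
  D <- length(config$sample_sizes)
  if (any(config$sample_sizes %% 2 != 0))
    stop("haploid sample sizes must be even to form diploids")
  if (is.null(deme_names)) deme_names <- paste0("pop", seq_len(D))
  ea <- engine_args(config)
  set.seed(derive_seed(config$seed, 0L))
  raw <- cpp_simulate_panel(ea$samples, ea$etimes, ea$sizes, ea$migs,
                            ea$merges, config$mu * config$locus_length,
                            config$n_loci)
  n_snp <- length(raw$locus)
  ntip <- sum(config$sample_sizes)
  n_ind <- ntip %/% 2L
  ind_deme <- rep(seq_len(D), config$sample_sizes %/% 2L)
  ids <- paste0(deme_names[ind_deme], "_",
                unlist(lapply(config$sample_sizes %/% 2L, seq_len)))
  if (n_snp == 0) {
    gm <- genotype_matrix(ids, deme_names[ind_deme],
                          matrix(integer(0), n_ind, 0), character(0),
                          locus_length = config$locus_length)
    attr(gm, "truth") <- config
    return(gm)
  }
  H <- matrix(0L, ntip, n_snp)
  snp_of_carrier <- rep(seq_len(n_snp), diff(raw$offsets))
  H[cbind(raw$carriers + 1L, snp_of_carrier)] <- 1L
  # random within-deme pairing, shared by all SNPs of a locus
  deme_of_tip <- rep(seq_len(D), config$sample_sizes)
  tips_of_deme <- split(seq_len(ntip), deme_of_tip)
  G <- matrix(0L, n_ind, n_snp)
  ind_of_deme <- split(seq_len(n_ind), ind_deme)
  snps_of_locus <- split(seq_len(n_snp), raw$locus)
  for (snps in snps_of_locus) {
    for (d in seq_len(D)) {
      perm <- sample(tips_of_deme[[d]])
      odd <- perm[seq(1, length(perm), by = 2)]
      even <- perm[seq(2, length(perm), by = 2)]
      G[ind_of_deme[[d]], snps] <-
        H[odd, snps, drop = FALSE] + H[even, snps, drop = FALSE]
    }
  }
  gm <- genotype_matrix(ids, deme_names[ind_deme], G,
                        paste0("locus_", raw$locus),
                        locus_length = config$locus_length)
  attr(gm, "truth") <- config
  gm
}

#' Superimpose allele dropout and locus-level missingness on a SNP panel
#'
#' With probability `dropout_rate` per individual-locus one haplotype is
#' silently lost, so heterozygous calls at the locus collapse to the
#' surviving homozygote (the surviving allele is drawn uniformly per
#' heterozygous site); with probability `missing_rate` per individual-locus
#' the genotypes of the locus become missing. Deterministic given `seed`.
#'
#' @param gm a [genotype_matrix()].
#' @param dropout_rate,missing_rate probabilities in `[0, 1]`.
#' @param seed integer seed.
#' @return a [genotype_matrix()] with perturbed calls.
#' @export
apply_dropout_and_missingness <- function(gm, dropout_rate, missing_rate, seed) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (dropout_rate < 0 || dropout_rate > 1 || missing_rate < 0 || missing_rate > 1)
    stop("rates must lie in [0, 1]")
  set.seed(derive_seed(seed, 0L))
  loci <- unique(gm$locus_id)
  n_ind <- length(gm$ids)
  locus_col <- match(gm$locus_id, loci)
  if (dropout_rate > 0 && ncol(gm$geno) > 0) {
    drop_il <- matrix(runif(n_ind * length(loci)) < dropout_rate,
                      n_ind, length(loci))
    sel <- drop_il[, locus_col, drop = FALSE] & !is.na(gm$geno) & gm$geno == 1L
    gm$geno[sel] <- 2L * rbinom(sum(sel), 1L, 0.5)
  }
  if (missing_rate > 0 && ncol(gm$geno) > 0) {
    miss_il <- matrix(runif(n_ind * length(loci)) < missing_rate,
                      n_ind, length(loci))
    gm$geno[miss_il[, locus_col, drop = FALSE]] <- NA_integer_
  }
  gm
}

#' Simulate a multi-colony mtDNA haplotype alignment
#'
#' Haploid n-island coalescent over the colonies with finite-sites
#' (Jukes-Cantor) mutation on a `seq_length`-bp fragment, so recurrent
#' mutation and haplotype reuse are possible, as appropriate for a short
#' mitochondrial marker. All samples share a single non-recombining
#' genealogy.
#'
#' @param colony_sizes named integer vector of samples per colony.
#' @param theta_per_site scaled mitochondrial diversity 2*N*mu per site.
#' @param migration_matrix scaled migration rates between colonies:
#'   entry `[i, j]` is `2*N*m` for lineages of colony i tracing into colony
#'   j (zero diagonal); a scalar is recycled to all off-diagonal entries.
#' @param seq_length fragment length in bp (default 900).
#' @param seed integer seed.
#' @param groups optional named map colony -> group (default: each colony
#'   its own group).
#' @param divergence time, in units of 2N generations, at which all
#'   colonies merge into a single ancestral pool (default 50; effectively
#'   deep isolation when migration is zero, irrelevant when migration is
#'   appreciable).
#' @return a [hap_alignment()].
#' @export
simulate_mtdna_colonies <- function(colony_sizes, theta_per_site,
                                    migration_matrix = 0, seq_length = 900,
                                    seed, groups = NULL, divergence = 50) {
  D <- length(colony_sizes)
  if (any(colony_sizes < 1)) stop("colony sizes must be positive")
  if (is.null(names(colony_sizes))) names(colony_sizes) <- paste0("C", seq_len(D))
  if (length(migration_matrix) == 1) {
    migration_matrix <- matrix(migration_matrix, D, D)
  }
  migration_matrix <- as.matrix(migration_matrix)
  diag(migration_matrix) <- 0
  if (any(migration_matrix < 0)) stop("migration rates must be nonnegative")
  N_hap <- 1e4 # internal haploid scale; only products theta, 2Nm matter
  mu_site <- theta_per_site / (2 * N_hap)
  mig <- migration_matrix / (2 * N_hap)
  Tdiv <- divergence * 2 * N_hap
  etimes <- c(0, Tdiv)
  sizes <- rbind(rep(N_hap, D), rep(N_hap, D))
  migs <- list(mig, matrix(0, D, D))
  merges <- if (D > 1) {
    cbind(Tdiv, seq_len(D - 1), 0) # all colonies into colony 1
  } else matrix(numeric(0), 0, 3)
  set.seed(derive_seed(seed, 0L))
  m <- cpp_simulate_seqs(as.integer(colony_sizes), etimes, sizes, migs,
                         merges, mu_site, as.integer(seq_length))
  bases <- c("A", "C", "G", "T")
  colony <- rep(names(colony_sizes), colony_sizes)
  ids <- paste0(colony, "_",
                unlist(lapply(colony_sizes, seq_len)))
  seqs <- apply(m, 1, function(r) paste0(bases[r + 1L], collapse = ""))
  grp <- if (is.null(groups)) colony else {
    if (!all(names(colony_sizes) %in% names(groups)))
      stop("groups must name every colony")
    unname(groups[colony])
  }
  hap_alignment(ids, seqs, colony, grp)
}
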