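# The study conditions: sampling design and generator defaults that emulate
# the empirical system — seven breeding colonies of a diving petrel sampled
# for a ~900-bp mitochondrial cytochrome-b fragment, and a two-island RAD
# SNP panel (11 + 10 diploid individuals, 95-bp loci).

#' Colony sampling design of the mtDNA survey
#'
#' Seven colonies with their sample sizes and the four island groups used by
#' the hierarchical AMOVA: the two Choros colonies (CHA, CHB), Isla Grande
#' de Atacama (IGA), the two Pan de Azucar colonies (AZA, AZB) and the two
#' Peruvian colonies (ILV, ISG).
#'
#' @return list with `sizes` (named integer vector, n = 109) and `groups`
#'   (named map colony -> group).
#' @export
colony_design <- function() {
  list(sizes = c(CHA = 32L, CHB = 11L, IGA = 7L, AZA = 27L, AZB = 11L,
                 ILV = 12L, ISG = 9L),
       groups = c(CHA = "CHR", CHB = "CHR", IGA = "IGA", AZA = "AZR",
                  AZB = "AZR", ILV = "PER", ISG = "PER"))
}

#' Simulate an mtDNA alignment under the study conditions
#'
#' Seven-colony island-model coalescent at the empirical sampling design,
#' with per-colony scaled diversity theta = 4e-4 per site and scaled
#' migration 2Nm = 10 within island groups and 0.15 between groups — a
#' strong-philopatry regime calibrated once to the scale of the empirical
#' fragment (~14 segregating sites over 900 bp pooled, group-level
#' Phi_ST around 0.27).
#'
#' @param seed integer seed.
#' @param theta_per_site per-colony scaled diversity (default 4e-4).
#' @param mig_within,mig_between scaled migration rates 2Nm within and
#'   between island groups (defaults 10 and 0.15).
#' @param seq_length fragment length (default 900 bp).
#' @return a [hap_alignment()] with the design's colony and group labels.
#' @export
simulate_study_mtdna <- function(seed, theta_per_site = 4e-4,
                                 mig_within = 10, mig_between = 0.15,
                                 seq_length = 900) {
  des <- colony_design()
  D <- length(des$sizes)
  m <- matrix(mig_between, D, D,
              dimnames = list(names(des$sizes), names(des$sizes)))
  for (g in unique(des$groups)) {
    cols <- names(des$groups)[des$groups == g]
    m[cols, cols] <- mig_within
  }
  diag(m) <- 0
  simulate_mtdna_colonies(des$sizes, theta_per_site, m, seq_length,
                          seed = seed, groups = des$groups)
}

#' Best-supported demographic parameters of the two-island system
#'
#' Point estimates (medians) of the selected migration-regime-change model
#' (model 4): constant sizes N_C = 91,350 and N_A = 1,013 diploids, old
#' migration M_AC = 2.756e-4 and M_CA = 1.146e-5, switching at T1 = 207
#' generations to M_AC = 4.268e-3 and M_CA = 1.170e-5, divergence fixed at
#' 7,000 generations.
#'
#' @param scale divide the deme sizes by this factor (e.g. 10 for
#'   reduced-scale simulation studies; times and migration rates are not
#'   rescaled).
#' @return named numeric vector of model-4 parameters.
#' @export
study_model4_params <- function(scale = 1) {
  c(N_C1 = 91350 / scale, N_A1 = 1013 / scale,
    M_AC0 = 2.756e-4, M_CA0 = 1.146e-5, T1 = 207,
    M_AC1 = 4.268e-3, M_CA1 = 1.170e-5)
}

#' Simulate the two-island SNP panel under the study conditions
#'
#' Model-4 demography at [study_model4_params()], sampled as 11 CHR + 10
#' AZR diploids over `n_loci` unlinked 95-bp RAD loci at mu = 9.6e-9.
#'
#' @param seed integer seed.
#' @param n_loci number of RAD loci (default 37170, the empirical
#'   polymorphic-locus count).
#' @param scale deme-size scaling factor passed to
#'   [study_model4_params()].
#' @param dropout_rate,missing_rate optional perturbations applied with
#'   [apply_dropout_and_missingness()] (defaults 0: clean panel).
#' @return a [genotype_matrix()] with populations `CHR` and `AZR`.
#' @export
simulate_study_snp_panel <- function(seed, n_loci = 37170, scale = 1,
                                     dropout_rate = 0, missing_rate = 0) {
  p <- study_model4_params(scale)
  cfg <- coalescent_config(
    c(22, 20), N = c(p[["N_C1"]], p[["N_A1"]]),
    M = {
      m <- matrix(0, 2, 2)
      m[2, 1] <- p[["M_AC1"]]; m[1, 2] <- p[["M_CA1"]]
      m
    },
    N_ancient = c(p[["N_C1"]], p[["N_A1"]]),
    M_ancient = {
      m <- matrix(0, 2, 2)
      m[2, 1] <- p[["M_AC0"]]; m[1, 2] <- p[["M_CA0"]]
      m
    },
    T0 = 7000, T1 = p[["T1"]], mu = 9.6e-9, locus_length = 95,
    n_loci = n_loci, seed = seed)
  gm <- simulate_snp_panel(cfg, deme_names = c("CHR", "AZR"))
  if (dropout_rate > 0 || missing_rate > 0)
    gm <- apply_dropout_and_missingness(gm, dropout_rate, missing_rate,
                                        seed = derive_seed(seed, 77L))
  gm
}
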