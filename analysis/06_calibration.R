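#!/usr/bin/env Rscript
# Mutation-rate calibration arithmetic: the per-generation background rate,
# the Poisson model of SNPs per RAD locus, the substitution-rate classes
# for highly polymorphic loci (S in 4..6), and the scaling of
# mutation-scaled estimates (Theta, M) to effective sizes and migrant
# numbers.
#
# Usage: Rscript analysis/06_calibration.R
# (uses results/data/snp.vcf for the empirical SNP-per-locus counts when
# present; the published anchors otherwise)

library(petrelpop)

out <- "results/calibration"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## background rate: 1.6e-3 subst/site/Myr, 6-year generation time -----------
mu <- per_generation_rate(1.6e-3, 6)
message("per-generation rate mu = ", format(mu, digits = 6))

## Poisson SNPs per locus -----------------------------------------------------
lambda <- 1.3 # published polymorphic-locus anchor
gof <- NULL
if (file.exists("results/data/snp.vcf")) {
  gm <- read_genotypes("results/data/snp.vcf", "results/data/snp.popmap",
                       max_missing_frac = 1)
  counts <- as.vector(table(gm$locus_id))
  gof <- fit_poisson_snp_counts(counts)
  message(sprintf("synthetic panel: lambda = %.3f over polymorphic loci (chi^2 GOF p = %.3g)",
                  gof$lambda, gof$p_value))
}

## class rates for S in 4..6 and their weighted average ----------------------
S <- 4:6
rates <- class_rate(S, lambda, mu)
w_pois <- dpois(S, lambda)           # truncated-Poisson weights
mu_hat_pois <- weighted_average(rates, w_pois)
mu_hat_flat <- weighted_average(rates, rep(1, 3))
tab <- data.frame(S = S, mu_S = rates)
print(tab, digits = 6)
message("weighted average (Poisson weights): ", format(mu_hat_pois, digits = 4),
        "; (equal weights): ", format(mu_hat_flat, digits = 4))

## scale Theta and M (published haplotype-based estimates) to Ne and Nm ------
theta_chr <- 0.00697; theta_azr <- 0.00747; M <- 2075
mu_rad <- 3.55e-8 # the published class-weighted rate for 4..6-SNP loci
scaled <- data.frame(
  quantity = c("Ne_CHR", "Ne_AZR", "Nm_CHR", "Nm_AZR"),
  value = c(scale_theta(theta_chr, mu_rad), scale_theta(theta_azr, mu_rad),
            scale_migrants(theta_chr, M), scale_migrants(theta_azr, M)))
print(scaled, digits = 6)

jsonlite::write_json(
  list(mu_per_generation = mu, lambda_anchor = lambda,
       lambda_synthetic = if (!is.null(gof)) gof$lambda else NULL,
       poisson_gof_p = if (!is.null(gof)) gof$p_value else NULL,
       class_rates = as.list(setNames(rates, paste0("S", S))),
       mu_weighted_poisson = mu_hat_pois, mu_weighted_equal = mu_hat_flat,
       scaled = as.list(setNames(scaled$value, scaled$quantity))),
  file.path(out, "calibration.json"), auto_unbox = TRUE, digits = NA)
message("wrote ", out)
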