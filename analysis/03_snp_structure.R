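#!/usr/bin/env Rscript
# Population structure from the two-island SNP panel: per-island diversity
# and Tajima's D, windowed Weir-Cockerham Fst, and the locus-by-locus
# hierarchical AMOVA (colonies within islands).
#
# Usage: Rscript analysis/03_snp_structure.R [seed]
# (expects results/data from 01_simulate.R)

library(petrelpop)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
out <- "results/snp"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

gm <- read_genotypes("results/data/snp.vcf", "results/data/snp.popmap",
                     max_missing_frac = 0.25)
truth <- jsonlite::read_json("results/data/truth.json")
total_sites <- truth$snp$n_loci * truth$snp$locus_length

## diversity and Tajima's D per island and pooled ----------------------------
units <- list(CHR = "CHR", AZR = "AZR", ALL = c("CHR", "AZR"))
tab <- do.call(rbind, lapply(names(units), function(u) {
  sub <- gm
  keep <- gm$population %in% units[[u]]
  sub$ids <- gm$ids[keep]; sub$population <- gm$population[keep]
  sub$geno <- gm$geno[keep, , drop = FALSE]
  st <- snp_summary(sub, total_sites)
  data.frame(unit = u, S = st$S, pi = st$pi, tajimas_D = st$D)
}))
write.table(format(tab, digits = 4), file.path(out, "snp_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(tab, digits = 3)

## windowed Fst ---------------------------------------------------------------
n_windows <- min(500, max(1, floor(ncol(gm$geno) / 20)))
wf <- windowed_fst(gm, n_windows = n_windows)
message(sprintf("Weir-Cockerham Fst = %.3f +/- %.3f over %d SNP windows",
                wf$mean, wf$sd, n_windows))

## locus-by-locus AMOVA (one SNP per locus, colonies in islands) -------------
# the synthetic popmap carries islands as populations; split each island
# into its two sampled colonies for the hierarchical design
gm1 <- one_snp_per_locus(gm)
colony <- gm1$population
for (isl in unique(gm1$population)) {
  idx <- which(gm1$population == isl)
  colony[idx] <- paste0(isl, rep(c("A", "B"), length.out = length(idx)))
}
gm1$population <- colony
groups <- setNames(sub("[AB]$", "", unique(colony)), unique(colony))
am <- amova_snp(gm1, groups, n_permutations = 2000, seed = seed)
print(am)

jsonlite::write_json(
  list(fst_mean = wf$mean, fst_sd = wf$sd, n_windows = n_windows,
       amova = list(sigma2 = as.list(am$sigma2),
                    percent = as.list(am$percent), phi = as.list(am$phi),
                    p = as.list(am$p))),
  file.path(out, "snp_structure.json"), auto_unbox = TRUE, digits = NA)
write_manifest(file.path(out, "manifest.json"),
               inputs = "results/data/snp.vcf",
               params = list(n_windows = n_windows, amova_permutations = 2000),
               seed = seed)
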