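#!/usr/bin/env Rscript
# Build the folded joint (2D) minor-allele frequency spectrum of the
# two-island SNP panel and its nonparametric locus block bootstrap
# replicates.
#
# Usage: Rscript analysis/04_sfs.R [seed] [n_bootstrap]
# (expects results/data from 01_simulate.R)

library(petrelpop)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
n_boot <- if (length(args) >= 2) as.integer(args[2]) else 20L
out <- "results/sfs"
dir.create(file.path(out, "bootstrap"), recursive = TRUE,
           showWarnings = FALSE)

gm <- read_genotypes("results/data/snp.vcf", "results/data/snp.popmap",
                     max_missing_frac = 0.25)
sfs <- folded_2dsfs(gm, "CHR", "AZR")
write_sfs(sfs, file.path(out, "observed.sfs"))
message("observed SFS: ", sfs$n1, " x ", sfs$n2, " haploid projection, ",
        round(sfs$n_snps_used), " SNPs used")

reps <- bootstrap_sfs(gm, n_boot, seed = seed, pop1 = "CHR", pop2 = "AZR",
                      n1 = sfs$n1, n2 = sfs$n2)
for (b in seq_along(reps)) {
  write_sfs(reps[[b]], file.path(out, "bootstrap",
                                 sprintf("replicate_%03d.sfs", b)))
}
message("wrote ", n_boot, " bootstrap replicates")
write_manifest(file.path(out, "manifest.json"),
               inputs = "results/data/snp.vcf",
               params = list(n_bootstrap = n_boot,
                             projection = c(sfs$n1, sfs$n2)), seed = seed)
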