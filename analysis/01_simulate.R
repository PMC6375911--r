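#!/usr/bin/env Rscript
# Generate the synthetic study data: a seven-colony mtDNA cytochrome-b
# alignment (n = 109, 900 bp) and a two-island RAD SNP panel (11 + 10
# diploids, 95-bp loci) simulated under the best-supported demographic
# model. Writes FASTA + popmap, VCF + popmap, and a truth JSON with every
# generator parameter.
#
# Usage: Rscript analysis/01_simulate.R [seed]

library(petrelpop)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## mtDNA panel ---------------------------------------------------------------
aln <- simulate_study_mtdna(seed = seed)
write_fasta_alignment(aln, file.path(out, "mtdna.fasta"),
                      file.path(out, "mtdna.popmap"))
message("mtDNA: ", length(aln$ids), " sequences x ", ncol(aln$seq), " bp, ",
        summary_stats(aln)$S, " segregating sites")

## SNP panel (scaled-down demography keeps this step light) ------------------
gm <- simulate_study_snp_panel(seed = seed, n_loci = 20000, scale = 10,
                               dropout_rate = 0.1, missing_rate = 0.1)
gm <- filter_missingness(gm, 0.25)
write_genotypes_vcf(gm, file.path(out, "snp.vcf"))
grp <- c(CHR = "CHR", AZR = "AZR")
writeLines(paste(gm$ids, gm$population, grp[gm$population], sep = "\t"),
           file.path(out, "snp.popmap"))
message("SNP panel: ", length(gm$ids), " individuals, ", ncol(gm$geno),
        " SNPs on ", length(unique(gm$locus_id)), " polymorphic loci")

truth <- list(
  seed = seed,
  mtdna = list(design = colony_design(), theta_per_site = 4e-4,
               mig_within = 10, mig_between = 0.15, seq_length = 900),
  snp = list(model = 4, params = as.list(study_model4_params(scale = 10)),
             T0 = 7000, mu = 9.6e-9, locus_length = 95, n_loci = 20000,
             dropout_rate = 0.1, missing_rate = 0.1))
jsonlite::write_json(truth, file.path(out, "truth.json"), auto_unbox = TRUE,
                     pretty = TRUE, digits = NA)
write_manifest(file.path(out, "manifest.json"),
               inputs = "none (simulation)",
               params = list(n_loci = 20000, scale = 10), seed = seed)
message("wrote ", out)
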