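#!/usr/bin/env Rscript
# Population structure from the mtDNA alignment: per-colony and pooled
# summary statistics, the pairwise Phi_ST matrix with Benjamini-Yekutieli
# corrected permutation p-values, the hierarchical AMOVA over the four
# island groups, and the Hamming distance matrix export.
#
# Usage: Rscript analysis/02_mtdna_structure.R [seed]
# (expects results/data from 01_simulate.R)

library(petrelpop)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
out <- "results/mtdna"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

aln <- read_fasta_alignment("results/data/mtdna.fasta",
                            "results/data/mtdna.popmap")

## summary statistics per colony and pooled (Table-2 layout) -----------------
units <- c(as.list(unique(aln$colony)), list(unique(aln$colony)))
names(units) <- c(unique(aln$colony), "ALL")
tab <- do.call(rbind, lapply(names(units), function(u) {
  st <- summary_stats(subset_colonies(aln, units[[u]]))
  data.frame(unit = u, n = st$n, H = st$H, pi = st$pi, K = st$K, S = st$S,
             tajimas_D = st$D)
}))
write.table(format(tab, digits = 4), file.path(out, "summary_stats.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(tab, digits = 3)

## pairwise Phi_ST with BY correction (Table-1 layout) -----------------------
pm <- phi_st_matrix(aln, n_permutations = 2000, seed = seed)
write.table(format(round(pm$matrix, 4)), file.path(out, "phi_st_matrix.tsv"),
            sep = "\t", quote = FALSE, col.names = NA)
write.table(format(pm$pairs, digits = 4), file.path(out, "phi_st_pairs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("pairwise Phi_ST: ", sum(pm$pairs$p_adjusted <= 0.05), " of ",
        nrow(pm$pairs), " comparisons significant after BY correction")

## hierarchical AMOVA over the four island groups ----------------------------
am <- amova(aln, n_permutations = 15000, seed = seed)
print(am)
jsonlite::write_json(
  list(sigma2 = as.list(am$sigma2), percent = as.list(am$percent),
       phi = as.list(am$phi), p = as.list(am$p),
       n_permutations = am$n_permutations),
  file.path(out, "amova.json"), auto_unbox = TRUE, digits = NA)

## Hamming distance matrix for network software ------------------------------
d <- pairwise_differences(aln)
write_distance_matrix(d, path = file.path(out, "hamming.phy"),
                      format = "phylip")
write_distance_matrix(d, path = file.path(out, "hamming.nex"),
                      format = "nexus")
write_manifest(file.path(out, "manifest.json"),
               inputs = "results/data/mtdna.fasta",
               params = list(amova_permutations = 15000,
                             pairwise_permutations = 2000), seed = seed)
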