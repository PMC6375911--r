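#!/usr/bin/env Rscript
# Fit the two-deme demographic models to the observed folded 2D SFS by
# composite likelihood, rank them by AIC, and bootstrap confidence
# intervals for the best model. Desk-scale budgets by default; pass
# "paper" as the third argument to restore the full published budget
# (50 runs, 80 ECM cycles, 1e5 genealogies per evaluation, 50 bootstraps —
# hours to days of CPU).
#
# Usage: Rscript analysis/05_demography.R [seed] [model_ids] [budget]
#   e.g. Rscript analysis/05_demography.R 1 "1,2,3,4" desk

library(petrelpop)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
ids <- if (length(args) >= 2) as.integer(strsplit(args[2], ",")[[1]]) else c(3L, 4L)
budget <- if (length(args) >= 3) args[3] else "desk"
stopifnot(budget %in% c("desk", "paper"))
bud <- if (budget == "paper") {
  list(n_runs = 50, max_cycles = 80, n_genealogies = 1e5, polish = 0,
       boot_runs = 50, n_boot = 50)
} else {
  list(n_runs = 6, max_cycles = 4, n_genealogies = 2000, polish = 300,
       boot_runs = 2, n_boot = 10)
}
out <- "results/demography"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

obs <- read_sfs("results/sfs/observed.sfs")
# scaled-down bounds matching the synthetic panel of 01_simulate.R
mk_model <- function(id) demographic_model(id, size_bounds = c(20, 5e4),
                                           mig_bounds = c(1e-7, 2e-2))

fits <- lapply(ids, function(id) {
  message("fitting model ", id, " (", budget, " budget)")
  fit_model(obs, mk_model(id), n_runs = bud$n_runs,
            max_cycles = bud$max_cycles,
            n_genealogies = bud$n_genealogies, seed = seed,
            line_evals = 5, polish_evals = bud$polish)
})
tab <- compare_models(fits)
print(tab, digits = 6)
write.table(format(tab, digits = 6), file.path(out, "aic_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  lapply(fits, function(f) list(model = f$model_id, k = f$k,
                                loglik = f$loglik, AIC = f$AIC,
                                par = as.list(f$par))),
  file.path(out, "fits.json"), auto_unbox = TRUE, digits = NA)

## bootstrap CIs for the AIC-best model --------------------------------------
best_id <- tab$model[1]
boot_files <- list.files("results/sfs/bootstrap", full.names = TRUE)
if (length(boot_files) >= 2) {
  reps <- lapply(utils::head(boot_files, bud$n_boot), read_sfs)
  ci <- bootstrap_cis(reps, mk_model(best_id), n_runs = bud$boot_runs,
                      max_cycles = bud$max_cycles,
                      n_genealogies = bud$n_genealogies, seed = seed,
                      polish_evals = bud$polish)
  print(ci, digits = 4)
  write.table(format(ci, digits = 6),
              file.path(out, sprintf("model%d_bootstrap_ci.tsv", best_id)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
write_manifest(file.path(out, "manifest.json"),
               inputs = "results/sfs/observed.sfs",
               params = c(bud, list(models = ids, budget = budget)),
               seed = seed)
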