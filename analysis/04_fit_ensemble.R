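#!/usr/bin/env Rscript
# Stage 4 — fit, evaluate, gate and ensemble.
#
# Six algorithms x 10 replicates of an 80/20 stratified split, AUC/TSS
# evaluation, gating at AUC >= 0.9 and TSS >= 0.7, permutation variable
# importance for the kept algorithms, and ensemble probability rasters for
# the reference period and every scenario.

suppressPackageStartupMessages(library(aridsuit))
out <- "results/analysis"
seed <- as.integer(readLines(file.path(out, "seed.txt")))
cfg <- pipeline_config(seed = seed)

table <- read.csv(file.path(out, "feature_table.csv"))
screen <- read.csv(file.path(out, "vif_screen.csv"))
vars <- screen$variable[screen$retained]

fits <- fit_all(table, vars, algorithms = cfg$modelling$algorithms,
                n_reps = cfg$modelling$n_reps,
                train_frac = cfg$modelling$train_frac, seed = seed + 4L)
gates <- gate(fits$evals, auc_min = cfg$modelling$auc_min,
              tss_min = cfg$modelling$tss_min)
write.csv(fits$evals, file.path(out, "model_evaluations.csv"),
          row.names = FALSE)
write.csv(gates, file.path(out, "gate_decisions.csv"), row.names = FALSE)

kept <- gates$algorithm[gates$kept]
cat("per-algorithm means (kept = passed AUC >= 0.9 and TSS >= 0.7):\n")
print(gates, row.names = FALSE)

imp <- importance_table(fits$scorers[kept], table, seed = seed + 5L)
write.csv(imp, file.path(out, "variable_importance.csv"), row.names = FALSE)
cat("top contributing variables:",
    paste(head(imp$variable, 3), collapse = ", "), "\n")

scorers <- unlist(fits$scorers[kept], recursive = FALSE)
periods <- c("reference", names(cfg$synthetic$scenarios))
for (period in periods) {
  lay <- c(
    lapply(setNames(c("elevation", "slope", "aspect"),
                    c("elevation", "slope", "aspect")), function(nm) {
      read_ascii_grid(file.path(out, paste0(nm, ".asc")))
    }),
    lapply(setNames(c("bio3", "bio4", "bio8", "bio9", "bio14", "bio19"),
                    c("bio3", "bio4", "bio8", "bio9", "bio14", "bio19")),
           function(nm) {
      read_ascii_grid(file.path(out, sprintf("%s_%s.asc", nm, period)))
    })
  )
  ens <- ensemble_predict(scorers, lay)
  write_ascii_grid(ens, file.path(out, sprintf("suitability_%s.asc", period)))
  cat(sprintf("%s: ensemble of %d scorers, mean probability %.3f\n",
              period, length(scorers), mean(ens$values)))
}
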