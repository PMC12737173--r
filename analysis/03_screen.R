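#!/usr/bin/env Rscript
# Stage 3 — multicollinearity screening.
#
# Iterative VIF pruning at threshold 5 on the covariate table, then the
# Pearson correlation matrix of the survivors.

suppressPackageStartupMessages(library(aridsuit))
out <- "results/analysis"
table <- read.csv(file.path(out, "feature_table.csv"))
vars <- setdiff(names(table), c("lon", "lat", "label"))

screen <- iterative_prune(table[, vars], threshold = 5)
write.csv(screen$table, file.path(out, "vif_screen.csv"), row.names = FALSE)
write.csv(as.data.frame(screen$pearson),
          file.path(out, "pearson_matrix.csv"))

cat(sprintf("screened %d candidate variables at VIF threshold 5\n",
            length(vars)))
if (nrow(screen$drop_order)) {
  cat("dropped:", paste(sprintf("%s (VIF %.1f)", screen$drop_order$variable,
                                screen$drop_order$vif_at_drop),
                        collapse = ", "), "\n")
} else cat("no variable exceeded the threshold\n")
cat("retained:", paste(screen$retained, collapse = ", "), "\n")
cat(sprintf("largest |r| among survivors: %.2f\n",
            max(abs(screen$pearson[upper.tri(screen$pearson)]))))
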