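#!/usr/bin/env Rscript
# Stage 7 — couple suitability with aridity.
#
# Frequency distribution of suitable habitat (moderate + high) across the
# UNEP aridity classes per period, and binomial logistic regression of
# habitat loss on the standardized aridity index per scenario.

suppressPackageStartupMessages({
  library(aridsuit)
  library(jsonlite)
})
out <- "results/analysis"
seed <- as.integer(readLines(file.path(out, "seed.txt")))
cfg <- pipeline_config(seed = seed)
periods <- c("reference", names(cfg$synthetic$scenarios))

areas <- cell_area_km2(read_ascii_grid(file.path(out, "elevation.asc")))
for (period in periods) {
  cls <- read_ascii_grid(file.path(out, sprintf("classes_%s.asc", period)))
  acls <- read_ascii_grid(file.path(out,
                                    sprintf("aridity_classes_%s.asc",
                                            period)))
  suit <- suitable_mask(cls)
  if (!any(suit)) {
    cat(period, ": no suitable habitat left; frequency table skipped\n")
    next
  }
  tab <- frequency_by_aridity(suit, acls, areas)
  write.csv(tab, file.path(out, sprintf("aridity_frequency_%s.csv", period)),
            row.names = FALSE)
  lead <- tab[order(-tab$percent), ][1:2, ]
  cat(sprintf("%s: suitable habitat mostly %s (%.1f%%) then %s (%.1f%%)\n",
              period, lead$label[1], lead$percent[1], lead$label[2],
              lead$percent[2]))
}

loss <- list()
for (nm in names(cfg$synthetic$scenarios)) {
  cm <- read_ascii_grid(file.path(out, sprintf("change_%s.asc", nm)))
  ai <- read_ascii_grid(file.path(out, sprintf("ai_%s.asc", nm)))
  fit <- fit_loss_logistic(cm, ai)
  loss[[nm]] <- fit[c("beta", "se", "p_value", "odds_ratio",
                      "pseudo_r2_pct", "auc", "n_cells", "n_loss")]
  cat(sprintf(
    "%s: beta %.4f (p %s), OR %.2f per SD aridity, pseudo-R2 %.1f%%, AUC %.3f\n",
    nm, fit$beta, ifelse(fit$p_value < 0.001, "<0.001",
                         sprintf("%.3f", fit$p_value)),
    fit$odds_ratio, fit$pseudo_r2_pct, fit$auc))
}
write_json(loss, file.path(out, "loss_regressions.json"), auto_unbox = TRUE,
           digits = NA)
cat("wrote", file.path(out, "loss_regressions.json"), "\n")
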