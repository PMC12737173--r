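#!/usr/bin/env Rscript
# Stage 5 — classify suitability and map gain/loss/stable change.
#
# Equal-interval four-class maps (bounds 0.25 / 0.5 / 0.75), km2 + percent
# area tables per period, and change maps of each scenario against the
# reference with "suitable" = moderate + high.

suppressPackageStartupMessages(library(aridsuit))
out <- "results/analysis"
seed <- as.integer(readLines(file.path(out, "seed.txt")))
cfg <- pipeline_config(seed = seed)
periods <- c("reference", names(cfg$synthetic$scenarios))

classmaps <- list()
for (period in periods) {
  prob <- read_ascii_grid(file.path(out,
                                    sprintf("suitability_%s.asc", period)))
  classmaps[[period]] <- classify_suitability(
    prob, bounds = cfg$classification$bounds)
  write_ascii_grid(classmaps[[period]],
                   file.path(out, sprintf("classes_%s.asc", period)))
  areas <- cell_area_km2(prob)
  tab <- class_areas(classmaps[[period]], areas)
  write.csv(tab, file.path(out, sprintf("areas_%s.csv", period)),
            row.names = FALSE)
  cat(sprintf("%s: %s\n", period,
              paste(sprintf("%s %.1f%%", tab$label, tab$percent),
                    collapse = ", ")))
}

areas <- cell_area_km2(classmaps$reference)
for (nm in names(cfg$synthetic$scenarios)) {
  cm <- change_map(classmaps$reference, classmaps[[nm]],
                   cutoff_class = cfg$classification$cutoff_class)
  write_ascii_grid(cm, file.path(out, sprintf("change_%s.asc", nm)))
  tab <- change_areas(cm, areas)
  write.csv(tab, file.path(out, sprintf("change_areas_%s.csv", nm)),
            row.names = FALSE)
  cat(sprintf("change %s: stable %.1f%%, gain %.1f%%, loss %.1f%%\n", nm,
              tab$percent[tab$label == "stable"],
              tab$percent[tab$label == "gain"],
              tab$percent[tab$label == "loss"]))
}
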