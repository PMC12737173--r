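#!/usr/bin/env Rscript
# Stage 6 — Thornthwaite PET and the UNEP Aridity Index per period.

suppressPackageStartupMessages(library(aridsuit))
out <- "results/analysis"
seed <- as.integer(readLines(file.path(out, "seed.txt")))
cfg <- pipeline_config(seed = seed)
spec <- cfg$synthetic$world
periods <- c("reference", names(cfg$synthetic$scenarios))

tmpl <- read_ascii_grid(file.path(out, "elevation.asc"))
lats <- synthetic_latitudes(tmpl, spec$origin_lat)

for (period in periods) {
  climate <- list(
    temp = lapply(1:12, function(m) {
      read_ascii_grid(file.path(out, sprintf("temp_%s_m%02d.asc", period, m)))
    }),
    precip = lapply(1:12, function(m) {
      read_ascii_grid(file.path(out,
                                sprintf("precip_%s_m%02d.asc", period, m)))
    })
  )
  pet <- thornthwaite_pet(climate, lats,
                          linear_term_sign = cfg$thornthwaite$linear_term_sign)
  p_annual <- annual_precip(climate$precip)
  ai <- unep_ai(p_annual, pet$annual_pet_mm)
  cls <- classify_ai(ai$ai, undefined = ai$undefined)
  write_ascii_grid(pet$annual_pet_mm,
                   file.path(out, sprintf("pet_annual_%s.asc", period)))
  write_ascii_grid(ai$ai, file.path(out, sprintf("ai_%s.asc", period)))
  write_ascii_grid(cls, file.path(out, sprintf("aridity_classes_%s.asc",
                                               period)))
  share <- table(factor(cls$values, levels = 0:5)) / length(cls$values)
  cat(sprintf(
    "%s: PET %.0f-%.0f mm, AI %.2f-%.2f; sub-humid %.0f%%, dry sub-humid %.0f%%, semi-arid %.0f%%\n",
    period, min(pet$annual_pet_mm$values), max(pet$annual_pet_mm$values),
    min(ai$ai$values, na.rm = TRUE), max(ai$ai$values, na.rm = TRUE),
    100 * share[["4"]], 100 * share[["3"]], 100 * share[["2"]]))
}
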