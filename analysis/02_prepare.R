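#!/usr/bin/env Rscript
# Stage 2 — occurrence preparation.
#
# Samples presences from the known truth surface, applies 5-km spatial
# rarefaction, draws pseudo-absences with 100-km spacing (one per
# 10,000 km2 neighbourhood), and extracts the covariate table.

suppressPackageStartupMessages(library(aridsuit))
out <- "results/analysis"
seed <- as.integer(readLines(file.path(out, "seed.txt")))
cfg <- pipeline_config(seed = seed)
spec <- cfg$synthetic$world

layer_names <- c("elevation", "slope", "aspect",
                 "bio3", "bio4", "bio8", "bio9", "bio14", "bio19")
lay <- c(
  lapply(setNames(layer_names[1:3], layer_names[1:3]), function(nm) {
    read_ascii_grid(file.path(out, paste0(nm, ".asc")))
  }),
  lapply(setNames(layer_names[-(1:3)], layer_names[-(1:3)]), function(nm) {
    read_ascii_grid(file.path(out, paste0(nm, "_reference.asc")))
  })
)

occ_raw <- sample_occurrences(cfg$synthetic$truth, lay,
                              n_presence = cfg$synthetic$n_presence,
                              seed = seed + 1L)
occ <- rarefy(occ_raw, cfg$prepare$presence_min_dist_km, seed = seed + 2L,
              crs = "local-km")
mask <- read_ascii_grid(file.path(out, "elevation.asc"))
mask$values[] <- 1
absences <- generate_pseudo_absences(
  mask, n_target = nrow(occ),
  min_dist_km = cfg$prepare$absence_min_dist_km, seed = seed + 3L,
  presences = occ, presence_buffer_km = cfg$prepare$presence_buffer_km)
table <- build_feature_table(occ, absences, lay)

write.csv(occ, file.path(out, "presences.csv"), row.names = FALSE)
write.csv(absences, file.path(out, "absences.csv"), row.names = FALSE)
write.csv(table, file.path(out, "feature_table.csv"), row.names = FALSE)

cat(sprintf("presences: %d raw -> %d after 5-km rarefaction\n",
            nrow(occ_raw), nrow(occ)))
cat(sprintf("pseudo-absences: %d placed at >= %g km spacing\n",
            nrow(absences), cfg$prepare$absence_min_dist_km))
cat(sprintf("feature table: %d rows x %d covariates (%d dropped on nodata)\n",
            nrow(table), length(layer_names),
            attr(table, "n_dropped_nodata")))
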