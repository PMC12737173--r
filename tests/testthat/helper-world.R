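# small fixture builders shared across test files

tiny_world <- function(seed = 1L, rows = 24, cols = 32, ...) {
  synthetic_world_spec(grid_rows = rows, grid_cols = cols, seed = seed,
                       spatial_corr_length_cells = 3, ...)
}

tiny_layers <- function(spec = tiny_world()) {
  terr <- generate_terrain(spec)
  nrm <- generate_monthly_normals(spec, elevation = terr$elevation)
  c(terr, derive_bioclim_subset(nrm$temp, nrm$precip,
                                diurnal_range_C = spec$diurnal_range_C))
}

flat_raster <- function(value = 1, rows = 10, cols = 10, cellsize = 1,
                        crs = "local-km", xmin = 0, ymin = 0) {
  raster_grid(matrix(value, rows, cols), xmin = xmin, ymin = ymin,
              cellsize = cellsize, crs = crs)
}

# constructed monthly normals with given per-month constants on a tiny grid
constant_normals <- function(temps, precips, rows = 8, cols = 8,
                             cellsize = 10) {
  tmpl <- flat_raster(0, rows, cols, cellsize = cellsize)
  list(
    temp = lapply(stats::setNames(1:12, sprintf("m%02d", 1:12)),
                  function(m) raster_grid(matrix(temps[m], rows, cols),
                                          cellsize = cellsize,
                                          crs = "local-km")),
    precip = lapply(stats::setNames(1:12, sprintf("m%02d", 1:12)),
                    function(m) raster_grid(matrix(precips[m], rows, cols),
                                            cellsize = cellsize,
                                            crs = "local-km"))
  )
}

# random labelled feature table with independent covariates
random_feature_table <- function(n = 200, p = 4, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("v", seq_len(p))))
  eta <- x[, 1] * 2 - x[, 2]
  data.frame(label = rbinom(n, 1, plogis(eta)), x)
}
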