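test_that("zero-noise normals equal the stated monthly means exactly", {
  spec <- tiny_world(noise_sd_temp_C = 0, noise_sd_precip_frac = 0,
                     monthly_temp_means_C = rep(20, 12),
                     monthly_precip_means_mm = rep(50, 12))
  nrm <- generate_monthly_normals(spec)
  expect_true(all(nrm$temp$m01$values == 20))
  expect_true(all(nrm$precip$m07$values == 50))
})

test_that("generation is deterministic given the seed", {
  a <- generate_monthly_normals(tiny_world(seed = 5))
  b <- generate_monthly_normals(tiny_world(seed = 5))
  expect_identical(a$temp$m06$values, b$temp$m06$values)
  expect_identical(a$precip$m12$values, b$precip$m12$values)
  c2 <- generate_monthly_normals(tiny_world(seed = 6))
  expect_false(identical(a$temp$m06$values, c2$temp$m06$values))
})

test_that("precipitation never goes negative after noise", {
  spec <- tiny_world(noise_sd_precip_frac = 2)   # huge noise forces clipping
  nrm <- generate_monthly_normals(spec)
  expect_true(all(vapply(nrm$precip, function(r) min(r$values), 0) >= 0))
})

test_that("fields carry the requested spatial autocorrelation", {
  spec <- synthetic_world_spec(grid_rows = 60, grid_cols = 60, seed = 9,
                               spatial_corr_length_cells = 5,
                               noise_sd_temp_C = 2)
  f <- generate_monthly_normals(spec)$temp$m01$values
  # lag-1 Moran-style correlation along rows and columns
  lag1 <- function(m) {
    cor(c(as.vector(m[, -1]), as.vector(m[-1, ])),
        c(as.vector(m[, -ncol(m)]), as.vector(m[-nrow(m), ])))
  }
  expect_gt(lag1(f), 0.5)
})

test_that("world spec validation rejects bad parameters", {
  expect_error(synthetic_world_spec(grid_rows = 4), "at least 8")
  expect_error(synthetic_world_spec(cell_size_km = 0), "positive")
  expect_error(synthetic_world_spec(spatial_corr_length_cells = -1),
               "positive")
})

test_that("bioclim summaries match brute-force quarter enumeration", {
  # asymmetric sinusoid temperature, winter-peaked precipitation
  temps <- 11 + 11 * sin(2 * pi * (1:12 - 4) / 12)
  precs <- 80 + 60 * cos(2 * pi * (1:12 - 1) / 12)
  nrm <- constant_normals(temps, precs)
  bio <- derive_bioclim_subset(nrm$temp, nrm$precip, diurnal_range_C = 10)

  # brute force over the 12 circular quarters
  q_idx <- lapply(1:12, function(s) ((s - 1 + 0:2) %% 12) + 1)
  qT <- vapply(q_idx, function(ii) mean(temps[ii]), 0)
  qP <- vapply(q_idx, function(ii) sum(precs[ii]), 0)
  expect_equal(bio$bio8$values[1, 1], qT[which.max(qP)])
  expect_equal(bio$bio9$values[1, 1], qT[which.min(qP)])
  expect_equal(bio$bio19$values[1, 1], qP[which.min(qT)])
  expect_equal(bio$bio14$values[1, 1], min(precs))
  expect_equal(bio$bio4$values[1, 1], 100 * sd(temps))
  expect_equal(bio$bio3$values[1, 1],
               100 * 10 / (max(temps) - min(temps)))
})

test_that("degenerate bioclim inputs behave as documented", {
  nrm <- constant_normals(rep(15, 12), rep(10, 12))
  bio <- derive_bioclim_subset(nrm$temp, nrm$precip)
  expect_equal(bio$bio4$values[1, 1], 0)        # zero seasonality
  expect_equal(bio$bio14$values[1, 1], 10)      # constant precipitation
  expect_true(is.na(bio$bio3$values[1, 1]))     # zero annual range flagged
})

test_that("scenario forcing shifts temperature and scales precipitation", {
  nrm <- constant_normals(1:12, rep(30, 12))
  fut <- apply_scenario(nrm, delta_T_C = 2, precip_factor = 0.8)
  expect_equal(fut$temp$m03$values[1, 1], 5)
  expect_equal(fut$precip$m03$values[1, 1], 24)
  expect_error(apply_scenario(nrm, 1, 0), "positive")
})

test_that("bio14 scales with the precipitation factor when ranking is stable", {
  spec <- tiny_world(seed = 11)
  terr <- generate_terrain(spec)
  nrm <- generate_monthly_normals(spec, elevation = terr$elevation)
  fut <- apply_scenario(nrm, 0, 0.85)
  b_ref <- derive_bioclim_subset(nrm$temp, nrm$precip)
  b_fut <- derive_bioclim_subset(fut$temp, fut$precip)
  # pure scaling preserves which month is driest, so bio14 scales exactly
  expect_equal(b_fut$bio14$values, 0.85 * b_ref$bio14$values,
               tolerance = 1e-12)
})

test_that("flat terrain has zero slope and the flat-aspect sentinel", {
  elev <- flat_raster(500, 10, 10, cellsize = 1)
  sa <- slope_aspect(elev)
  expect_true(all(sa$slope$values == 0))
  expect_true(all(sa$aspect$values == -1))
})

test_that("a planar ramp rising due east has westward downslope aspect", {
  nr <- 12; nc <- 12; cs <- 1
  ramp <- raster_grid(matrix(rep((1:nc) * 100, each = nr), nr, nc),
                      cellsize = cs, crs = "local-km")
  sa <- slope_aspect(ramp)
  inner <- sa$aspect$values[2:(nr - 1), 2:(nc - 1)]
  expect_true(all(abs(inner - 270) < 1e-9))
  # slope tangent = rise/run = 100 m per 1000 m
  inner_slope <- sa$slope$values[2:(nr - 1), 2:(nc - 1)]
  expect_equal(unique(round(as.vector(tan(inner_slope * pi / 180)), 10)),
               0.1)
  # doubling the cell size halves the tangent on the same values
  ramp2 <- raster_grid(ramp$values, cellsize = 2 * cs, crs = "local-km")
  sa2 <- slope_aspect(ramp2)
  expect_equal(tan(sa2$slope$values[5, 5] * pi / 180),
               tan(sa$slope$values[5, 5] * pi / 180) / 2, tolerance = 1e-12)
})

test_that("presences are drawn where the truth model is suitable", {
  lay <- tiny_layers(tiny_world(seed = 21))
  tm <- truth_model(c(elevation = 8), intercept = -8 * 700)  # uphill niche
  occ <- sample_occurrences(tm, lay, 150, seed = 4)
  ft <- extract_covariates(occ, lay["elevation"])
  expect_gt(mean(ft$elevation), mean(lay$elevation$values))
  # determinism
  occ2 <- sample_occurrences(tm, lay, 150, seed = 4)
  expect_identical(occ, occ2)
  expect_error(sample_occurrences(tm, lay, 1e6, seed = 1), "exceeds")
})

test_that("a flat truth model samples uniformly over the grid", {
  lay <- tiny_layers(tiny_world(seed = 3, rows = 50, cols = 50))
  tm <- truth_model(c(elevation = 0), intercept = 0)
  occ <- sample_occurrences(tm, lay, 2000, seed = 8)
  # chi-square GOF on a 5x5 coarse binning of the 50x50 grid
  bx <- cut(occ$lon, breaks = seq(0, 500, by = 100))
  by <- cut(occ$lat, breaks = seq(0, 500, by = 100))
  p <- chisq.test(table(bx, by))$p.value
  expect_gt(p, 0.01)
})

test_that("GLM on truth-model data recovers coefficient signs", {
  lay <- tiny_layers(tiny_world(seed = 13, rows = 50, cols = 60))
  tm <- truth_model(c(elevation = -0.01, bio19 = 0.05),
                    intercept = 0.01 * 700 - 0.05 * 335)
  suit <- true_suitability(tm, lay)
  sm <- stack_matrix(lay[c("elevation", "bio19")])
  set.seed(31)
  rows <- sample(nrow(sm$x), 2000, replace = TRUE)
  y <- rbinom(2000, 1, suit$values[sm$cells][rows])
  fit <- glm(y ~ sm$x[rows, 1] + sm$x[rows, 2], family = binomial())
  expect_lt(coef(fit)[2], 0)
  expect_gt(coef(fit)[3], 0)
})

test_that("lapse-rate coupling cools high ground", {
  spec <- tiny_world(seed = 17, noise_sd_temp_C = 0)
  terr <- generate_terrain(spec)
  nrm <- generate_monthly_normals(spec, elevation = terr$elevation)
  t1 <- nrm$temp$m07$values
  hi <- terr$elevation$values > quantile(terr$elevation$values, 0.8)
  lo <- terr$elevation$values < quantile(terr$elevation$values, 0.2)
  expect_lt(mean(t1[hi]), mean(t1[lo]))
  # spatial mean stays at the stated monthly mean
  expect_equal(mean(t1), spec$monthly_temp_means_C[7], tolerance = 1e-9)
})

test_that("synthetic latitudes anchor the south edge at origin_lat", {
  r <- flat_raster(1, 10, 10, cellsize = 10)
  lats <- synthetic_latitudes(r, origin_lat = 36)
  expect_equal(length(lats), 10)
  expect_lt(lats[10], lats[1])                     # row 1 is northernmost
  expect_equal(lats[10], 36 + 5 / (6371.0088 * pi / 180), tolerance = 1e-12)
})
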