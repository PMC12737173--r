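#' Specification of a synthetic study region
#'
#' The synthetic world is a projected square grid (kilometre units,
#' `crs = "local-km"`) carrying twelve monthly mean-temperature and twelve
#' monthly total-precipitation normals, each the stated monthly mean plus a
#' spatially autocorrelated Gaussian field. Defaults emulate a
#' Mediterranean-type climate on a region of roughly Anatolian extent:
#' winter-peaked precipitation, summer-peaked temperature, 10 km cells.
#'
#' @param grid_rows,grid_cols grid dimensions (each >= 8).
#' @param cell_size_km cell edge length in km.
#' @param seed integer seed making every generated layer reproducible.
#' @param spatial_corr_length_cells Gaussian correlation length of the noise
#'   fields, in cells.
#' @param monthly_temp_means_C 12 monthly mean temperatures (deg C, Jan-Dec).
#' @param monthly_precip_means_mm 12 monthly total precipitations (mm, >= 0).
#' @param noise_sd_temp_C standard deviation of the temperature noise field.
#' @param noise_sd_precip_frac precipitation noise sd as a fraction of the
#'   monthly mean; fields are clipped at 0 after noise.
#' @param origin_lat latitude (deg N) assigned to the southern grid edge,
#'   used to derive per-row latitudes for day-length computations.
#' @param diurnal_range_C fixed diurnal temperature range injected into the
#'   isothermality layer (daily extremes are not simulated).
#' @param lapse_rate_C_per_km environmental lapse rate coupling temperature
#'   to elevation when an elevation surface is supplied to
#'   [generate_monthly_normals()]; 0 disables the coupling.
#' @return a `synthetic_world_spec` list.
#' @export
synthetic_world_spec <- function(grid_rows = 60, grid_cols = 90,
                                 cell_size_km = 10, seed = 1L,
                                 spatial_corr_length_cells = 6,
                                 monthly_temp_means_C =
                                   c(5, 6, 9, 13, 18, 23, 26, 28, 24, 18, 12, 7),
                                 monthly_precip_means_mm =
                                   c(120, 100, 80, 60, 40, 20, 8, 8, 30, 70, 100, 130),
                                 noise_sd_temp_C = 3,
                                 noise_sd_precip_frac = 0.35,
                                 origin_lat = 36,
                                 diurnal_range_C = 10,
                                 lapse_rate_C_per_km = 6.5) {
  if (grid_rows < 8 || grid_cols < 8) {
    stop("grid must be at least 8 x 8 cells", call. = FALSE)
  }
  if (cell_size_km <= 0) stop("cell_size_km must be positive", call. = FALSE)
  if (spatial_corr_length_cells <= 0) {
    stop("spatial_corr_length_cells must be positive", call. = FALSE)
  }
  stopifnot(length(monthly_temp_means_C) == 12L,
            length(monthly_precip_means_mm) == 12L,
            all(monthly_precip_means_mm >= 0),
            noise_sd_temp_C >= 0, noise_sd_precip_frac >= 0,
            diurnal_range_C > 0)
  structure(
    list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         cell_size_km = cell_size_km, seed = as.integer(seed),
         spatial_corr_length_cells = spatial_corr_length_cells,
         monthly_temp_means_C = monthly_temp_means_C,
         monthly_precip_means_mm = monthly_precip_means_mm,
         noise_sd_temp_C = noise_sd_temp_C,
         noise_sd_precip_frac = noise_sd_precip_frac,
         origin_lat = origin_lat, diurnal_range_C = diurnal_range_C,
         lapse_rate_C_per_km = lapse_rate_C_per_km),
    class = "synthetic_world_spec"
  )
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# spatially correlated Gaussian field: white noise circularly convolved
# (FFT) with a Gaussian kernel of sd = corr_length cells, standardized to
# empirical mean 0 / sd 1 so that mean + sd * field has exactly the stated
# moments within each realization
gaussian_random_field <- function(nr, nc, corr_length) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (corr_length <= 0.5) return((z - mean(z)) / stats::sd(z))
  kr <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1))
  kc <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1))
  d2 <- outer(kr^2, rep(1, nc)) + outer(rep(1, nr), kc^2)
  k <- exp(-d2 / (2 * corr_length^2))
  sm <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) / (nr * nc)
  (sm - mean(sm)) / stats::sd(sm)
}

world_template <- function(spec) {
  raster_grid(matrix(0, spec$grid_rows, spec$grid_cols),
              xmin = 0, ymin = 0, cellsize = spec$cell_size_km,
              crs = "local-km")
}

#' Generate monthly climate normals for a synthetic world
#'
#' Each monthly layer is the specified monthly mean plus an independent
#' spatially correlated Gaussian field scaled to the requested noise sd;
#' precipitation noise scales with the monthly mean and layers are clipped
#' at zero. When an elevation surface is supplied, temperatures additionally
#' decrease with elevation at the spec's lapse rate (anomaly relative to the
#' mean elevation, so the stated monthly means remain the spatial means).
#' Deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_world_spec()].
#' @param elevation optional aligned elevation `raster_grid` (m) enabling
#'   the lapse-rate coupling of temperature to terrain.
#' @return list with elements `temp` and `precip`, each a named list of 12
#'   `raster_grid`s (`"m01"`..`"m12"`).
#' @export
generate_monthly_normals <- function(spec, elevation = NULL) {
  stopifnot(inherits(spec, "synthetic_world_spec"))
  tmpl <- world_template(spec)
  nr <- spec$grid_rows; nc <- spec$grid_cols
  lapse_term <- 0
  if (!is.null(elevation)) {
    check_aligned(tmpl, elevation)
    dz_km <- (elevation$values - mean(elevation$values, na.rm = TRUE)) / 1000
    lapse_term <- -spec$lapse_rate_C_per_km * dz_km
  }
  with_local_seed(spec$seed, {
    temp <- vector("list", 12L); precip <- vector("list", 12L)
    for (m in 1:12) {
      f <- gaussian_random_field(nr, nc, spec$spatial_corr_length_cells)
      temp[[m]] <- new_like(tmpl, spec$monthly_temp_means_C[m] + lapse_term +
                              spec$noise_sd_temp_C * f)
    }
    for (m in 1:12) {
      f <- gaussian_random_field(nr, nc, spec$spatial_corr_length_cells)
      mu <- spec$monthly_precip_means_mm[m]
      v <- pmax(mu + spec$noise_sd_precip_frac * mu * f, 0)
      precip[[m]] <- new_like(tmpl, v)
    }
    names(temp) <- sprintf("m%02d", 1:12)
    names(precip) <- sprintf("m%02d", 1:12)
    list(temp = temp, precip = precip)
  })
}

#' Future-scenario forcing of a climate normal set
#'
#' Emulates SSP-style forcing as a uniform warming added to every monthly
#' temperature and a multiplicative factor on every monthly precipitation.
#'
#' @param normals output of [generate_monthly_normals()] (or same shape).
#' @param delta_T_C warming in deg C added to all months.
#' @param precip_factor positive multiplier on all monthly precipitation.
#' @return a normals list of the same shape.
#' @export
apply_scenario <- function(normals, delta_T_C, precip_factor) {
  if (!is.numeric(precip_factor) || precip_factor <= 0) {
    stop("precip_factor must be positive", call. = FALSE)
  }
  list(
    temp = lapply(normals$temp, function(r) new_like(r, r$values + delta_T_C)),
    precip = lapply(normals$precip,
                    function(r) new_like(r, r$values * precip_factor))
  )
}

# circular 3-consecutive-month quarters, Dec-Jan-Feb wraparound included
quarter_index <- function(start) ((start - 1L + 0:2) %% 12L) + 1L

#' Derive the retained bioclimatic layers from monthly normals
#'
#' Computes the six bioclimatic summaries used as climate predictors:
#' * `bio3` isothermality, `100 * diurnal_range / (max monthly T - min monthly T)`
#'   with a fixed configurable diurnal range (daily extremes are not part of
#'   the monthly normals);
#' * `bio4` temperature seasonality, `100 * sd` of the 12 monthly means;
#' * `bio8` / `bio9` mean temperature of the wettest / driest consecutive
#'   3-month quarter (circular, ties to the earliest starting month);
#' * `bio14` precipitation of the driest month;
#' * `bio19` precipitation total of the coldest quarter.
#'
#' @param monthly_T,monthly_P lists of 12 aligned `raster_grid`s.
#' @param diurnal_range_C fixed diurnal range (deg C) injected into `bio3`.
#' @return named list of `raster_grid`s: bio3, bio4, bio8, bio9, bio14, bio19.
#' @export
derive_bioclim_subset <- function(monthly_T, monthly_P, diurnal_range_C = 10) {
  stopifnot(length(monthly_T) == 12L, length(monthly_P) == 12L)
  tmpl <- monthly_T[[1L]]
  for (r in c(monthly_T, monthly_P)) check_aligned(tmpl, r)
  nr <- nrow(tmpl$values); nc <- ncol(tmpl$values)
  tarr <- vapply(monthly_T, function(r) r$values, matrix(0, nr, nc))
  parr <- vapply(monthly_P, function(r) r$values, matrix(0, nr, nc))
  dim(tarr) <- c(nr * nc, 12L); dim(parr) <- c(nr * nc, 12L)

  tmax <- apply(tarr, 1L, max); tmin <- apply(tarr, 1L, min)
  trange <- tmax - tmin
  bio3 <- ifelse(trange > 0, 100 * diurnal_range_C / trange, NA_real_)
  bio4 <- 100 * apply(tarr, 1L, stats::sd)
  bio14 <- apply(parr, 1L, min)

  qsel <- vapply(1:12, quarter_index, integer(3))   # 3 x 12 month indices
  qT <- vapply(1:12, function(q) rowMeans(tarr[, qsel[, q], drop = FALSE]),
               numeric(nr * nc))
  qP <- vapply(1:12, function(q) rowSums(parr[, qsel[, q], drop = FALSE]),
               numeric(nr * nc))
  wettest <- max.col(qP, ties.method = "first")
  driest <- max.col(-qP, ties.method = "first")
  coldest <- max.col(-qT, ties.method = "first")
  idx <- cbind(seq_len(nr * nc), wettest)
  bio8 <- qT[idx]
  bio9 <- qT[cbind(seq_len(nr * nc), driest)]
  bio19 <- qP[cbind(seq_len(nr * nc), coldest)]

  out <- lapply(list(bio3 = bio3, bio4 = bio4, bio8 = bio8, bio9 = bio9,
                     bio14 = bio14, bio19 = bio19),
                function(v) new_like(tmpl, matrix(v, nr, nc)))
  # propagate nodata from inputs
  nas <- Reduce(`|`, lapply(c(monthly_T, monthly_P),
                            function(r) is.na(r$values)))
  lapply(out, function(r) { r$values[nas] <- NA_real_; r })
}

#' Generate synthetic terrain: elevation, slope and aspect
#'
#' Elevation is a smooth random surface (long-correlation Gaussian field,
#' clipped at sea level). Slope (degrees) and aspect (degrees clockwise from
#' north of the downslope direction, range \[0, 360)) are computed by Horn's
#' finite-difference method on the 3x3 neighbourhood, with edge rows/columns
#' replicated. Flat cells receive the aspect sentinel.
#'
#' @param spec a [synthetic_world_spec()].
#' @param elev_mean,elev_sd mean and sd (m) of the elevation surface.
#' @param flat_aspect sentinel aspect for zero-gradient cells (default -1).
#' @return named list of `raster_grid`s: elevation, slope, aspect.
#' @export
generate_terrain <- function(spec, elev_mean = 700, elev_sd = 550,
                             flat_aspect = -1) {
  stopifnot(inherits(spec, "synthetic_world_spec"))
  tmpl <- world_template(spec)
  elev <- with_local_seed(spec$seed + 101L, {
    f <- gaussian_random_field(spec$grid_rows, spec$grid_cols,
                               2 * spec$spatial_corr_length_cells)
    pmax(elev_mean + elev_sd * f, 0)
  })
  elev_r <- new_like(tmpl, elev)
  sa <- slope_aspect(elev_r, flat_aspect = flat_aspect)
  list(elevation = elev_r, slope = sa$slope, aspect = sa$aspect)
}

#' Slope and aspect by Horn's method
#'
#' @param elev elevation `raster_grid` (values in metres).
#' @param flat_aspect aspect value assigned where the gradient is zero.
#' @return list of `raster_grid`s `slope` (degrees) and `aspect` (degrees
#'   clockwise from north of the downslope direction).
#' @export
slope_aspect <- function(elev, flat_aspect = -1) {
  stopifnot(is_raster_grid(elev))
  z <- elev$values
  nr <- nrow(z); nc <- ncol(z)
  # replicate-pad edges so the 3x3 window exists everywhere
  zp <- z[c(1, 1:nr, nr), c(1, 1:nc, nc)]
  run <- if (is_geographic(elev)) {
    stop("slope_aspect expects a projected grid", call. = FALSE)
  } else elev$cellsize * 1000   # metres
  at <- function(dr, dc) zp[(1:nr) + 1 + dr, (1:nc) + 1 + dc]
  # compass neighbours; matrix row increases southward
  a <- at(-1, -1); b <- at(-1, 0); cc <- at(-1, 1)
  d <- at(0, -1);                  f <- at(0, 1)
  g <- at(1, -1);  h <- at(1, 0);  i <- at(1, 1)
  dzdx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * run)   # +east
  dzdy <- ((a + 2 * b + cc) - (g + 2 * h + i)) / (8 * run)   # +north
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  down_e <- -dzdx; down_n <- -dzdy
  asp <- (atan2(down_e, down_n) * 180 / pi) %% 360
  flat <- dzdx == 0 & dzdy == 0
  asp[flat] <- flat_aspect
  nas <- is.na(z)
  slope[nas] <- NA_real_; asp[nas] <- NA_real_
  list(slope = new_like(elev, slope), aspect = new_like(elev, asp))
}

#' Ground-truth suitability model
#'
#' A logistic suitability surface over named environmental layers:
#' `suitability = plogis(intercept + sum(coef_l * layer_l))`. Used to sample
#' synthetic presences and as the recovery target for end-to-end tests.
#'
#' @param coefficients named numeric vector (layer name -> coefficient); at
#'   least one coefficient must be nonzero.
#' @param intercept scalar intercept on the logit scale.
#' @return a `truth_model` object.
#' @export
truth_model <- function(coefficients, intercept = 0) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
            all(nzchar(names(coefficients))))
  # an all-zero coefficient vector gives a flat (uniform) surface; allowed
  # because null-signal sampling is a supported test condition
  structure(list(coefficients = coefficients, intercept = intercept),
            class = "truth_model")
}

#' Evaluate a truth model over a layer stack
#'
#' @param truth a [truth_model()].
#' @param stack named list of aligned `raster_grid`s containing every layer
#'   named in the truth coefficients.
#' @return `raster_grid` of true suitability in \[0, 1\].
#' @export
true_suitability <- function(truth, stack) {
  stopifnot(inherits(truth, "truth_model"))
  miss <- setdiff(names(truth$coefficients), names(stack))
  if (length(miss)) stop("truth layers missing from stack: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  sm <- stack_matrix(stack[names(truth$coefficients)])
  eta <- truth$intercept + drop(sm$x %*% truth$coefficients)
  raster_from_cells(sm$template, sm$cells, stats::plogis(eta))
}

#' Sample presence points from a truth model
#'
#' Presence cells are drawn without replacement from the non-nodata cells of
#' the stack, with selection probability proportional to the true logistic
#' suitability. Points are returned as cell-center coordinates.
#'
#' @param truth a [truth_model()].
#' @param stack named list of aligned layers (must include truth layers).
#' @param n_presence number of presence points.
#' @param seed integer seed.
#' @return data.frame with columns `lon`, `lat` (grid coordinates of cell
#'   centers; km for synthetic grids, degrees for geographic ones).
#' @export
sample_occurrences <- function(truth, stack, n_presence, seed) {
  suit <- true_suitability(truth, stack)
  ok <- !is.na(suit$values)
  n_cells <- sum(ok)
  if (n_presence > n_cells) {
    stop("n_presence exceeds the number of available cells (", n_cells, ")",
         call. = FALSE)
  }
  w <- suit$values[ok]
  idx <- which(ok)                      # column-major cell indices
  pick <- with_local_seed(seed,
                          sample(seq_along(idx), n_presence, replace = FALSE,
                                 prob = w))
  cells <- idx[pick]
  rows <- ((cells - 1L) %% nrow(suit$values)) + 1L
  cols <- ((cells - 1L) %/% nrow(suit$values)) + 1L
  data.frame(lon = cell_centers_x(suit)[cols],
             lat = cell_centers_y(suit)[rows])
}

#' Per-row latitudes of a synthetic grid
#'
#' Converts row-center y offsets (km) of a projected synthetic grid to
#' latitudes, anchoring the southern edge at `origin_lat`. One degree of
#' latitude is `EARTH_RADIUS_KM * pi / 180` km.
#'
#' @param r a projected `raster_grid`.
#' @param origin_lat latitude of the southern grid edge (deg N).
#' @return numeric vector of latitudes, one per matrix row (north first).
#' @export
synthetic_latitudes <- function(r, origin_lat) {
  stopifnot(is_raster_grid(r), !is_geographic(r))
  km_per_deg <- EARTH_RADIUS_KM * pi / 180
  origin_lat + cell_centers_y(r) / km_per_deg
}
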