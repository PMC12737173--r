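#' Pairwise point distances in kilometres
#'
#' Distances are CRS-aware: great-circle (haversine, mean Earth radius
#' 6371.0088 km) for geographic coordinates, Euclidean for projected
#' kilometre grids.
#'
#' @param a,b two-column matrices/data.frames of coordinates (`lon`, `lat`
#'   degrees, or x/y km).
#' @param crs `"EPSG:4326"` or `"local-km"`.
#' @return matrix of distances, `nrow(a)` by `nrow(b)`, in km.
#' @export
point_distance_km <- function(a, b, crs = "EPSG:4326") {
  a <- as.matrix(a)[, 1:2, drop = FALSE]
  b <- as.matrix(b)[, 1:2, drop = FALSE]
  if (identical(crs, "EPSG:4326")) {
    rad <- pi / 180
    lat1 <- a[, 2] * rad; lat2 <- b[, 2] * rad
    lon1 <- a[, 1] * rad; lon2 <- b[, 1] * rad
    dlat <- outer(lat1, lat2, function(x, y) (y - x) / 2)
    dlon <- outer(lon1, lon2, function(x, y) (y - x) / 2)
    h <- sin(dlat)^2 +
      outer(cos(lat1), cos(lat2)) * sin(dlon)^2
    2 * EARTH_RADIUS_KM * asin(pmin(sqrt(h), 1))
  } else {
    dx <- outer(a[, 1], b[, 1], `-`)
    dy <- outer(a[, 2], b[, 2], `-`)
    sqrt(dx^2 + dy^2)
  }
}

#' Spatial rarefaction of occurrence points
#'
#' Greedy thinning: points are shuffled with `seed`, then accepted one by one
#' iff at least `min_dist_km` from every already-accepted point. Reduces
#' sampling bias and spatial autocorrelation in presence records. An empty
#' input returns an empty set.
#'
#' @param points data.frame with `lon`, `lat` columns.
#' @param min_dist_km minimum pairwise distance to enforce (> 0).
#' @param seed integer seed for the shuffle order.
#' @param crs coordinate system of the points (see [point_distance_km()]).
#' @return data.frame of retained points (same columns as input).
#' @export
rarefy <- function(points, min_dist_km, seed = 1L, crs = "EPSG:4326") {
  if (min_dist_km <= 0) stop("min_dist_km must be positive", call. = FALSE)
  n <- nrow(points)
  if (is.null(n) || n == 0L) return(points[0L, , drop = FALSE])
  ord <- with_local_seed(seed, sample.int(n))
  pts <- as.matrix(points[ord, c("lon", "lat")])
  keep <- logical(n)
  keep[1L] <- TRUE
  for (i in seq_len(n)[-1L]) {
    d <- point_distance_km(pts[i, , drop = FALSE],
                           pts[keep, , drop = FALSE], crs = crs)
    keep[i] <- all(d >= min_dist_km)
  }
  points[sort(ord[keep]), , drop = FALSE]
}

#' Generate pseudo-absence points with coarse spatial filtering
#'
#' Absences stand in for areas unsuitable for cultivation when only presence
#' records exist. Candidate cells are all mask cells at least
#' `presence_buffer_km` from every presence; candidates are shuffled with
#' `seed` and accepted greedily while at least `min_dist_km` from every
#' accepted absence, until `n_target` points are placed or candidates are
#' exhausted. The default 100 km spacing is the side of a 10,000 km2 square
#' (one absence per coarse neighbourhood).
#'
#' @param mask study-area mask `raster_grid`.
#' @param n_target desired number of absences (the result has at most this
#'   many; exactly this many when `min_dist_km = 0` and enough cells exist).
#' @param min_dist_km minimum pairwise distance between absences (>= 0).
#' @param seed integer seed.
#' @param presences optional data.frame of presence points (`lon`, `lat`).
#' @param presence_buffer_km exclusion radius around each presence.
#' @return data.frame with `lon`, `lat` of absence cell centers.
#' @export
generate_pseudo_absences <- function(mask, n_target, min_dist_km = 100,
                                     seed = 1L, presences = NULL,
                                     presence_buffer_km = 5) {
  inside <- mask_cells(mask)
  idx <- which(inside)
  rows <- ((idx - 1L) %% nrow(mask$values)) + 1L
  cols <- ((idx - 1L) %/% nrow(mask$values)) + 1L
  cand <- cbind(lon = cell_centers_x(mask)[cols],
                lat = cell_centers_y(mask)[rows])
  if (!is.null(presences) && nrow(presences) > 0L && presence_buffer_km > 0) {
    d <- point_distance_km(cand, presences[, c("lon", "lat")], crs = mask$crs)
    cand <- cand[apply(d, 1L, min) > presence_buffer_km, , drop = FALSE]
  }
  if (nrow(cand) == 0L) {
    stop("no mask cell lies outside the presence buffer; cannot place absences",
         call. = FALSE)
  }
  ord <- with_local_seed(seed, sample.int(nrow(cand)))
  cand <- cand[ord, , drop = FALSE]
  if (min_dist_km <= 0) {
    out <- cand[seq_len(min(n_target, nrow(cand))), , drop = FALSE]
    return(as.data.frame(out))
  }
  acc <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(cand))) {
    if (nrow(acc) >= n_target) break
    if (nrow(acc) == 0L ||
        all(point_distance_km(cand[i, , drop = FALSE], acc,
                              crs = mask$crs) >= min_dist_km)) {
      acc <- rbind(acc, cand[i, , drop = FALSE])
    }
  }
  out <- as.data.frame(acc)
  names(out) <- c("lon", "lat")
  rownames(out) <- NULL
  out
}

#' Extract covariate values at points
#'
#' Containing-cell lookup of every layer in the stack at each point. Points
#' falling outside the raster extent, or on a nodata cell of any layer, are
#' dropped; the drop counts are attached as attributes and reported with a
#' warning/message.
#'
#' @param points data.frame with `lon`, `lat` and optionally `label`.
#' @param stack named list of aligned `raster_grid`s.
#' @return data.frame (`feature_table`): `lon`, `lat`, `label` (if supplied)
#'   plus one column per layer; attributes `n_dropped_nodata`,
#'   `n_dropped_outside`.
#' @export
extract_covariates <- function(points, stack) {
  stopifnot(is.list(stack), length(stack) >= 1L)
  tmpl <- stack[[1L]]
  for (r in stack) check_aligned(tmpl, r)
  nrst <- nrow(tmpl$values); ncst <- ncol(tmpl$values)
  col <- floor((points$lon - tmpl$xmin) / tmpl$cellsize) + 1L
  row_from_s <- floor((points$lat - tmpl$ymin) / tmpl$cellsize) + 1L
  row <- nrst - row_from_s + 1L
  outside <- col < 1L | col > ncst | row < 1L | row > nrst
  if (any(outside)) {
    warning(sum(outside), " point(s) outside the raster extent were dropped",
            call. = FALSE)
  }
  keep <- !outside
  vals <- vapply(stack,
                 function(r) r$values[cbind(row[keep], col[keep])],
                 numeric(sum(keep)))
  if (!is.matrix(vals)) vals <- matrix(vals, ncol = length(stack),
                                       dimnames = list(NULL, names(stack)))
  on_nodata <- rowSums(is.na(vals)) > 0L
  out <- cbind(points[keep, , drop = FALSE][!on_nodata, , drop = FALSE],
               as.data.frame(vals[!on_nodata, , drop = FALSE]))
  rownames(out) <- NULL
  attr(out, "n_dropped_nodata") <- sum(on_nodata)
  attr(out, "n_dropped_outside") <- sum(outside)
  out
}

#' Assemble a presence/absence feature table
#'
#' Binds labelled presences (1) and absences (0) and extracts covariates;
#' rows on nodata are dropped and counted.
#'
#' @param presences,absences data.frames with `lon`, `lat`.
#' @param stack named list of aligned layers.
#' @return feature table as in [extract_covariates()] with a `label` column.
#' @export
build_feature_table <- function(presences, absences, stack) {
  pts <- rbind(
    cbind(presences[, c("lon", "lat")], label = 1),
    cbind(absences[, c("lon", "lat")], label = 0)
  )
  extract_covariates(pts, stack)
}
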