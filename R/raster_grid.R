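#' Lightweight single-band raster grid
#'
#' `raster_grid` is the data model used throughout the pipeline: a numeric
#' matrix of cell values (row 1 is the northernmost row, column 1 the
#' westernmost column), a cell-center-registered affine transform restricted
#' to square cells, a CRS tag, and nodata represented as `NA`.
#'
#' Two kinds of grid are supported:
#' * geographic (`crs = "EPSG:4326"`): coordinates in decimal degrees,
#'   cell areas computed from spherical geometry;
#' * projected/synthetic (`crs = "local-km"`): coordinates in kilometres on a
#'   plane, every cell has area `cellsize^2` km2.
#'
#' @param values numeric matrix; `NA` marks nodata cells.
#' @param xmin x coordinate of the western edge of the grid.
#' @param ymin y coordinate of the southern edge of the grid.
#' @param cellsize cell edge length (degrees or km, per `crs`); must be > 0.
#' @param crs CRS tag, `"EPSG:4326"` (default) or `"local-km"`.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, xmin = 0, ymin = 0, cellsize = 1,
                        crs = "EPSG:4326") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cellsize) || length(cellsize) != 1L || !is.finite(cellsize) ||
      cellsize <= 0) {
    stop("`cellsize` must be a single positive number", call. = FALSE)
  }
  if (!is.character(crs) || length(crs) != 1L || !nzchar(crs)) {
    stop("`crs` tag is missing", call. = FALSE)
  }
  structure(
    list(values = values, xmin = as.numeric(xmin), ymin = as.numeric(ymin),
         cellsize = as.numeric(cellsize), crs = crs),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("raster_grid: %d x %d cells, cellsize %g, crs %s\n",
              nrow(v), ncol(v), x$cellsize, x$crs))
  cat(sprintf("  extent x [%g, %g]  y [%g, %g]  nodata cells: %d\n",
              x$xmin, x$xmin + ncol(v) * x$cellsize,
              x$ymin, x$ymin + nrow(v) * x$cellsize, sum(is.na(v))))
  invisible(x)
}

#' @rdname raster_grid
#' @param x object to test.
#' @export
is_raster_grid <- function(x) inherits(x, "raster_grid")

is_geographic <- function(r) identical(r$crs, "EPSG:4326")

#' Cell-center coordinates
#'
#' @param r a `raster_grid`.
#' @return `cell_centers_x`: vector of column-center x coordinates (west to
#'   east); `cell_centers_y`: vector of row-center y coordinates ordered like
#'   the matrix rows (north to south).
#' @export
cell_centers_x <- function(r) {
  r$xmin + (seq_len(ncol(r$values)) - 0.5) * r$cellsize
}

#' @rdname cell_centers_x
#' @export
cell_centers_y <- function(r) {
  ny <- nrow(r$values)
  r$ymin + (ny - seq_len(ny) + 0.5) * r$cellsize
}

#' Check that two grids share one grid definition
#'
#' Alignment is exact transform + shape equality; the pipeline never
#' resamples silently.
#'
#' @param a,b `raster_grid` objects.
#' @param tol numeric tolerance on the transform components.
#' @return invisibly `TRUE`; stops with an alignment error otherwise.
#' @export
check_aligned <- function(a, b, tol = 1e-9) {
  stopifnot(is_raster_grid(a), is_raster_grid(b))
  ok <- identical(dim(a$values), dim(b$values)) &&
    abs(a$xmin - b$xmin) <= tol && abs(a$ymin - b$ymin) <= tol &&
    abs(a$cellsize - b$cellsize) <= tol && identical(a$crs, b$crs)
  if (!ok) stop("rasters are not aligned (transform/shape/crs differ)",
                call. = FALSE)
  invisible(TRUE)
}

new_like <- function(template, values) {
  raster_grid(matrix(values, nrow = nrow(template$values)),
              xmin = template$xmin, ymin = template$ymin,
              cellsize = template$cellsize, crs = template$crs)
}

#' Read / write a raster as an ESRI ASCII grid
#'
#' The on-disk format is the plain-text ESRI ASCII grid (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value` header followed by
#' row-major values, north row first). A one-line sidecar `<path>.crs` holds
#' the CRS tag; when absent on read, the `crs` argument is used. The
#' round-trip preserves values, transform and nodata to full double
#' precision (values are written with 17 significant digits).
#'
#' @param path file path.
#' @param crs CRS tag to assume when no sidecar file is present.
#' @return `read_ascii_grid`: a `raster_grid`.
#' @export
read_ascii_grid <- function(path, crs = "EPSG:4326") {
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(path, skip = 6L, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop("ASCII grid body has ", length(vals), " values, expected ", nr * nc,
         call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  crs_file <- paste0(path, ".crs")
  if (file.exists(crs_file)) crs <- trimws(readLines(crs_file, n = 1L))
  raster_grid(m, xmin = hdr$xllcorner, ymin = hdr$yllcorner,
              cellsize = hdr$cellsize, crs = crs)
}

#' @rdname read_ascii_grid
#' @param r a `raster_grid` to write.
#' @param nodata numeric value standing for `NA` on disk (default -9999).
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  stopifnot(is_raster_grid(r))
  v <- r$values
  if (any(v == nodata, na.rm = TRUE)) {
    stop("raster contains the nodata sentinel ", nodata, " as a real value",
         call. = FALSE)
  }
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10f", r$xmin),
    sprintf("yllcorner %.10f", r$ymin),
    sprintf("cellsize %.12f", r$cellsize),
    sprintf("NODATA_value %g", nodata)
  )
  body <- apply(v, 1L, function(row) paste(format(row, digits = 17,
                                                  trim = TRUE,
                                                  scientific = FALSE),
                                           collapse = " "))
  writeLines(c(hdr, body), path)
  writeLines(r$crs, paste0(path, ".crs"))
  invisible(path)
}

#' Per-cell area in square kilometres
#'
#' For geographic grids each cell's area follows the spherical formula
#' `(dlon * pi/180 * R * cos(lat)) * (dlat * pi/180 * R)` with
#' `R = 6371.0088` km evaluated at the cell-center latitude. For
#' projected/synthetic grids every cell has `cellsize^2` km2.
#'
#' @param r a `raster_grid`.
#' @return a `raster_grid` of per-cell areas (km2); nodata cells stay `NA`.
#' @export
cell_area_km2 <- function(r) {
  stopifnot(is_raster_grid(r))
  nr <- nrow(r$values); nc <- ncol(r$values)
  if (is_geographic(r)) {
    lat <- cell_centers_y(r)
    if (any(abs(lat) > 90)) stop("cell latitude beyond +/-90 degrees",
                                 call. = FALSE)
    rad <- pi / 180
    band <- (r$cellsize * rad * EARTH_RADIUS_KM * cos(lat * rad)) *
      (r$cellsize * rad * EARTH_RADIUS_KM)
    area <- matrix(rep(band, nc), nrow = nr, ncol = nc)
  } else {
    area <- matrix(r$cellsize^2, nrow = nr, ncol = nc)
  }
  area[is.na(r$values)] <- NA_real_
  new_like(r, area)
}

EARTH_RADIUS_KM <- 6371.0088

#' Study-area mask
#'
#' A mask is a `raster_grid` whose non-`NA` values are interpreted as logical
#' (non-zero = inside the study area). `apply_mask` sets cells outside the
#' mask to nodata and leaves inside values untouched.
#'
#' @param r raster to mask.
#' @param mask a mask `raster_grid` aligned with `r`.
#' @return masked `raster_grid`.
#' @export
apply_mask <- function(r, mask) {
  check_aligned(r, mask)
  inside <- mask_cells(mask)
  v <- r$values
  v[!inside] <- NA_real_
  new_like(r, v)
}

#' @rdname apply_mask
#' @return `mask_cells`: logical matrix, `TRUE` inside the mask.
#' @export
mask_cells <- function(mask) {
  stopifnot(is_raster_grid(mask))
  inside <- !is.na(mask$values) & mask$values != 0
  if (!any(inside)) stop("mask has no cells inside the study area",
                         call. = FALSE)
  inside
}

#' Flatten an aligned raster stack into a covariate matrix
#'
#' @param stack named list of aligned `raster_grid`s.
#' @param cells optional logical matrix selecting cells; defaults to cells
#'   that are non-nodata in every layer.
#' @return list with `x` (cells-by-layers numeric matrix), `cells` (logical
#'   matrix of retained cells) and `template` (first layer, for rebuilding).
#' @export
stack_matrix <- function(stack, cells = NULL) {
  stopifnot(is.list(stack), length(stack) >= 1L,
            !is.null(names(stack)), all(nzchar(names(stack))))
  template <- stack[[1L]]
  for (r in stack) check_aligned(template, r)
  ok <- Reduce(`&`, lapply(stack, function(r) !is.na(r$values)))
  if (!is.null(cells)) ok <- ok & cells
  x <- vapply(stack, function(r) r$values[ok], numeric(sum(ok)))
  if (!is.matrix(x)) x <- matrix(x, ncol = length(stack),
                                 dimnames = list(NULL, names(stack)))
  list(x = x, cells = ok, template = template)
}

#' Rebuild a raster from values on selected cells
#'
#' @param template `raster_grid` supplying the grid definition.
#' @param cells logical matrix of cells the values belong to.
#' @param values numeric vector, one per `TRUE` cell of `cells`.
#' @return `raster_grid` with `values` placed on `cells`, `NA` elsewhere.
#' @export
raster_from_cells <- function(template, cells, values) {
  stopifnot(sum(cells) == length(values))
  v <- matrix(NA_real_, nrow = nrow(template$values),
              ncol = ncol(template$values))
  v[cells] <- values
  new_like(template, v)
}

#' Area accounting over a classified raster
#'
#' Sums per-cell areas by integer class and reports percentages of the total
#' masked area. Classes listed in `classes` are always present in the output
#' (0 km2 rather than a missing row). Percentages use half-up rounding to
#' one decimal, matching conventional area tables.
#'
#' @param classmap `raster_grid` of integer class codes (`NA` = outside).
#' @param cell_areas `raster_grid` of per-cell km2 (from [cell_area_km2()]).
#' @param classes integer vector of class codes the table must contain;
#'   defaults to the sorted codes present.
#' @param labels optional character labels, parallel to `classes`.
#' @return data.frame with columns `class`, `label`, `km2`, `percent`.
#' @export
area_table <- function(classmap, cell_areas, classes = NULL, labels = NULL) {
  check_aligned(classmap, cell_areas)
  inside <- !is.na(classmap$values) & !is.na(cell_areas$values)
  cls <- classmap$values[inside]
  ar <- cell_areas$values[inside]
  if (is.null(classes)) classes <- sort(unique(cls))
  km2 <- vapply(classes, function(k) sum(ar[cls == k]), numeric(1))
  total <- sum(ar)
  pct <- round_half_up(100 * km2 / total, 1)
  if (is.null(labels)) labels <- as.character(classes)
  data.frame(class = classes, label = labels, km2 = km2, percent = pct,
             stringsAsFactors = FALSE)
}

# round half away from zero, as printed area tables do (base round() is
# round-half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
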