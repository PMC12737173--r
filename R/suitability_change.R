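#' Suitability class codes
#'
#' Equal-interval four-class scheme on ensemble probability: 0 unsuitable
#' (p < 0.25), 1 low (0.25 <= p < 0.5), 2 moderate (0.5 <= p < 0.75),
#' 3 high (p >= 0.75). Boundaries are inclusive upward.
#' @format NULL
#' @export
SUITABILITY_CLASSES <- c(unsuitable = 0L, low = 1L, moderate = 2L, high = 3L)

#' Classify a continuous suitability raster
#'
#' @param prob probability `raster_grid` with values in \[0, 1\] (or nodata).
#' @param bounds strictly increasing class bounds in (0, 1); default
#'   `c(0.25, 0.5, 0.75)`.
#' @return `raster_grid` of integer codes 0..3 (see [SUITABILITY_CLASSES]).
#' @export
classify_suitability <- function(prob, bounds = c(0.25, 0.5, 0.75)) {
  stopifnot(is_raster_grid(prob), length(bounds) == 3L,
            all(diff(bounds) > 0), bounds[1] > 0, bounds[3] < 1)
  v <- prob$values
  if (any(v < 0 | v > 1, na.rm = TRUE)) {
    stop("probability raster has values outside [0, 1]", call. = FALSE)
  }
  cls <- (v >= bounds[1]) + (v >= bounds[2]) + (v >= bounds[3])
  new_like(prob, cls)
}

#' Area accounting of suitability classes
#'
#' @param classmap class-code `raster_grid` from [classify_suitability()].
#' @param cell_areas per-cell km2 raster (see [cell_area_km2()]).
#' @return data.frame `class`, `label`, `km2`, `percent` over the four
#'   suitability classes; percents use the full masked area as denominator.
#' @export
class_areas <- function(classmap, cell_areas) {
  area_table(classmap, cell_areas, classes = unname(SUITABILITY_CLASSES),
             labels = names(SUITABILITY_CLASSES))
}

#' Change-category codes
#'
#' 0 unsuitable in both periods, 1 stable (suitable in both), 2 gain
#' (suitable only in the future), 3 loss (suitable only in the reference).
#' @format NULL
#' @export
CHANGE_CLASSES <- c(unsuitable = 0L, stable = 1L, gain = 2L, loss = 3L)

#' Gain/loss/stable change map between two class maps
#'
#' Binarizes each class map as suitable iff `class >= cutoff_class`
#' (default moderate, i.e. the moderate + high classes), then crosses the
#' two periods: stable where suitable in both, gain where only the future is
#' suitable, loss where only the reference is.
#'
#' @param reference,future aligned class-code `raster_grid`s.
#' @param cutoff_class lowest class counting as suitable (code or name).
#' @return `raster_grid` of change codes (see [CHANGE_CLASSES]).
#' @export
change_map <- function(reference, future, cutoff_class = "moderate") {
  check_aligned(reference, future)
  if (is.character(cutoff_class)) {
    cutoff_class <- SUITABILITY_CLASSES[[cutoff_class]]
  }
  rs <- reference$values >= cutoff_class
  fs <- future$values >= cutoff_class
  v <- ifelse(rs & fs, CHANGE_CLASSES[["stable"]],
              ifelse(!rs & fs, CHANGE_CLASSES[["gain"]],
                     ifelse(rs & !fs, CHANGE_CLASSES[["loss"]],
                            CHANGE_CLASSES[["unsuitable"]])))
  v[is.na(reference$values) | is.na(future$values)] <- NA_real_
  new_like(reference, v)
}

#' Area accounting of change categories
#'
#' @param changemap change-code raster from [change_map()].
#' @param cell_areas per-cell km2 raster.
#' @return data.frame over the four change categories (0 km2 rows included).
#' @export
change_areas <- function(changemap, cell_areas) {
  area_table(changemap, cell_areas, classes = unname(CHANGE_CLASSES),
             labels = names(CHANGE_CLASSES))
}

#' Percentages from printed class areas
#'
#' Recomputes the percent column of an area table from km2 values alone
#' (denominator = total), with half-up rounding to one decimal — the
#' arithmetic used to present area tables.
#'
#' @param km2 numeric vector of class areas.
#' @return numeric vector of percentages summing to ~100.
#' @export
percent_of_total <- function(km2) {
  stopifnot(all(km2 >= 0), sum(km2) > 0)
  round_half_up(100 * km2 / sum(km2), 1)
}
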