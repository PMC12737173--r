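DAYS_IN_MONTH <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
# day-of-year of each month's middle day (non-leap calendar)
MID_MONTH_DOY <- cumsum(c(0L, DAYS_IN_MONTH[-12L])) + (DAYS_IN_MONTH + 1L) %/% 2L

# mean day length (hours) at latitude phi (deg) on day-of-year J:
# declination delta = 0.4093 sin(2 pi (284 + J) / 365), sunset hour angle
# omega = acos(clamp(-tan(phi) tan(delta), -1, 1)), N = 24 omega / pi
day_length_hours <- function(latitude, doy) {
  delta <- 0.4093 * sin(2 * pi * (284 + doy) / 365)
  x <- -tan(latitude * pi / 180) * tan(delta)
  omega <- acos(pmin(1, pmax(-1, x)))
  24 * omega / pi
}

#' Thornthwaite day-length/month-length correction factor
#'
#' `AdjF = (N / 12) * (d / 30)` where `N` is the mean day length in hours for
#' the month's middle day (solar-declination model; day length clamps to
#' \[0, 24\] beyond the polar circles) and `d` the number of days in the
#' month (non-leap calendar).
#'
#' @param latitude latitude in degrees (scalar or vector).
#' @param month month number 1..12.
#' @return correction factor(s), positive.
#' @export
day_length_factor <- function(latitude, month) {
  if (any(month < 1L | month > 12L) || any(month != as.integer(month))) {
    stop("month must be an integer in 1..12", call. = FALSE)
  }
  month <- as.integer(month)
  n <- day_length_hours(latitude, MID_MONTH_DOY[month])
  (n / 12) * (DAYS_IN_MONTH[month] / 30)
}

# canonical Thornthwaite exponent a(I); `linear_sign` = +1 uses the canonical
# +1.7912e-2 I term, -1 the (typo-prone) printed negative variant
thornthwaite_exponent <- function(I, linear_sign = 1) {
  6.75e-7 * I^3 - 7.71e-5 * I^2 + linear_sign * 1.7912e-2 * I + 0.49239
}

#' Thornthwaite potential evapotranspiration on rasters
#'
#' Per cell: `Td = max(Tm, 0)`; annual heat index
#' `I = sum_m (Td_m / 5)^1.514`; exponent
#' `a = 6.75e-7 I^3 - 7.71e-5 I^2 + 1.7912e-2 I + 0.49239`; monthly
#' `PET = 16 * AdjF * (10 Td / I)^a` mm, defined as 0 where `Td = 0`;
#' annual PET is the sum over months. Cells with `I = 0` (all months at or
#' below freezing) get PET 0 and are flagged.
#'
#' @param climate list with `temp` and `precip`: 12 aligned `raster_grid`s
#'   each (precipitation is carried along untouched; only `temp` enters PET).
#' @param latitudes per-row latitudes (degrees), length = grid rows, used for
#'   the day-length correction — or a single scalar.
#' @param linear_term_sign `"canonical"` (default) for the `+1.7912e-2 I`
#'   term of the exponent polynomial, `"as_printed"` for the negative
#'   variant some sources print.
#' @return list: `monthly_pet_mm` (12 rasters), `annual_pet_mm`,
#'   `heat_index_I`, `exponent_a` (rasters), `frozen` (logical matrix of
#'   I = 0 cells).
#' @export
thornthwaite_pet <- function(climate, latitudes,
                             linear_term_sign = c("canonical", "as_printed")) {
  linear_term_sign <- match.arg(linear_term_sign)
  sgn <- if (linear_term_sign == "canonical") 1 else -1
  temps <- climate$temp
  stopifnot(length(temps) == 12L)
  tmpl <- temps[[1L]]
  for (r in temps) check_aligned(tmpl, r)
  nr <- nrow(tmpl$values); nc <- ncol(tmpl$values)
  if (length(latitudes) == 1L) latitudes <- rep(latitudes, nr)
  stopifnot(length(latitudes) == nr)

  td <- lapply(temps, function(r) pmax(r$values, 0))
  I <- Reduce(`+`, lapply(td, function(m) (m / 5)^1.514))
  a <- thornthwaite_exponent(I, linear_sign = sgn)
  monthly <- vector("list", 12L)
  annual <- matrix(0, nr, nc)
  for (m in 1:12) {
    adjf <- day_length_factor(latitudes, m)          # one value per row
    base <- 10 * td[[m]] / I
    pet <- 16 * adjf * ifelse(td[[m]] > 0 & I > 0, base^a, 0)
    pet[td[[m]] == 0 | I == 0] <- 0
    pet[is.na(temps[[m]]$values)] <- NA_real_
    monthly[[m]] <- new_like(tmpl, pet)
    annual <- annual + pet
  }
  names(monthly) <- sprintf("m%02d", 1:12)
  list(monthly_pet_mm = monthly,
       annual_pet_mm = new_like(tmpl, annual),
       heat_index_I = new_like(tmpl, I),
       exponent_a = new_like(tmpl, a),
       frozen = I == 0)
}

#' Annual precipitation total
#'
#' @param precip list of 12 aligned monthly precipitation rasters (mm).
#' @return `raster_grid` of annual totals.
#' @export
annual_precip <- function(precip) {
  stopifnot(length(precip) == 12L)
  tmpl <- precip[[1L]]
  for (r in precip) check_aligned(tmpl, r)
  new_like(tmpl, Reduce(`+`, lapply(precip, function(r) r$values)))
}

#' UNEP Aridity Index
#'
#' `AI = P / PET` (annual totals). Cells with `PET = 0` are energy-limited:
#' the ratio is undefined there, so they are flagged and later classified
#' Humid.
#'
#' @param annual_precip_mm,annual_pet_mm aligned `raster_grid`s.
#' @return list: `ai` (`raster_grid`, `NA` where PET = 0 or nodata),
#'   `undefined` (logical matrix of flagged PET = 0 cells).
#' @export
unep_ai <- function(annual_precip_mm, annual_pet_mm) {
  check_aligned(annual_precip_mm, annual_pet_mm)
  p <- annual_precip_mm$values
  pet <- annual_pet_mm$values
  if (any(p < 0, na.rm = TRUE)) {
    stop("negative annual precipitation", call. = FALSE)
  }
  undef <- !is.na(pet) & pet == 0
  ai <- ifelse(pet > 0, p / pet, NA_real_)
  ai[is.na(p) | is.na(pet)] <- NA_real_
  list(ai = new_like(annual_precip_mm, ai), undefined = undef)
}

#' Aridity class codes
#'
#' UNEP classification, lower-inclusive intervals:
#' 0 hyper-arid \[0, 0.05), 1 arid \[0.05, 0.2), 2 semi-arid \[0.2, 0.5),
#' 3 dry sub-humid \[0.5, 0.65), 4 sub-humid \[0.65, 1\], 5 humid (> 1).
#' @format NULL
#' @export
ARIDITY_CLASSES <- c(hyper_arid = 0L, arid = 1L, semi_arid = 2L,
                     dry_sub_humid = 3L, sub_humid = 4L, humid = 5L)

#' Classify a UNEP Aridity Index raster
#'
#' @param ai AI `raster_grid` (values >= 0 or nodata).
#' @param undefined optional logical matrix of PET = 0 cells; they are
#'   classified Humid (energy-limited convention).
#' @return `raster_grid` of class codes 0..5 (see [ARIDITY_CLASSES]).
#' @export
classify_ai <- function(ai, undefined = NULL) {
  stopifnot(is_raster_grid(ai))
  v <- ai$values
  if (any(v < 0, na.rm = TRUE)) stop("AI must be nonnegative", call. = FALSE)
  cls <- (v >= 0.05) + (v >= 0.2) + (v >= 0.5) + (v >= 0.65) + (v > 1)
  if (!is.null(undefined)) cls[undefined] <- ARIDITY_CLASSES[["humid"]]
  new_like(ai, cls)
}
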