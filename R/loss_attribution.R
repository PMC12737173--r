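#' Binary suitable-habitat mask
#'
#' Suitable habitat = moderate + high suitability classes.
#'
#' @param classmap suitability class-code `raster_grid`.
#' @return logical matrix, `TRUE` on suitable cells (`FALSE` on nodata).
#' @export
suitable_mask <- function(classmap) {
  stopifnot(is_raster_grid(classmap))
  m <- !is.na(classmap$values) &
    classmap$values >= SUITABILITY_CLASSES[["moderate"]]
  m
}

#' Frequency distribution of suitable habitat across aridity classes
#'
#' Area-weighted percentage of the suitable-habitat area falling in each
#' aridity class; every class is present in the output (0.0 rather than a
#' missing row).
#'
#' @param suitable logical matrix of suitable cells (see [suitable_mask()]).
#' @param aridity_classes aridity class-code `raster_grid`.
#' @param cell_areas per-cell km2 `raster_grid`.
#' @return data.frame: `aridity_class`, `label`, `km2`, `percent` (percents
#'   half-up rounded to one decimal, summing to ~100).
#' @export
frequency_by_aridity <- function(suitable, aridity_classes, cell_areas) {
  check_aligned(aridity_classes, cell_areas)
  stopifnot(identical(dim(suitable), dim(aridity_classes$values)))
  sel <- suitable & !is.na(aridity_classes$values) &
    !is.na(cell_areas$values)
  if (!any(sel)) stop("no suitable cells with defined aridity", call. = FALSE)
  cls <- aridity_classes$values[sel]
  ar <- cell_areas$values[sel]
  codes <- unname(ARIDITY_CLASSES)
  km2 <- vapply(codes, function(k) sum(ar[cls == k]), numeric(1))
  data.frame(aridity_class = codes, label = names(ARIDITY_CLASSES),
             km2 = km2, percent = round_half_up(100 * km2 / sum(km2), 1),
             stringsAsFactors = FALSE)
}

#' Logistic regression of habitat loss on the aridity index
#'
#' Cells coded `loss` in the change map become 1, every other masked cell 0;
#' the (by default standardized) UNEP AI is the single predictor of a
#' binomial logistic regression fitted by maximum likelihood. Because AI
#' decreases as aridity increases, the odds ratio per one-SD increase in
#' aridity is `exp(-beta)`. Reported alongside: Wald p-value, McFadden
#' pseudo-R2 (x100) and in-sample AUC of the fitted probabilities.
#'
#' @param changemap change-code `raster_grid` (see [change_map()]).
#' @param ai aridity-index `raster_grid` (same grid); cells with undefined
#'   AI are excluded and counted.
#' @param standardize center/scale AI before fitting (default `TRUE`).
#' @return a `loss_regression` list: `beta`, `se`, `p_value`, `odds_ratio`,
#'   `pseudo_r2_pct`, `auc`, `n_cells`, `n_loss`, `n_excluded_undefined_ai`,
#'   `standardization` (mean, sd), `separation` flag.
#' @export
fit_loss_logistic <- function(changemap, ai, standardize = TRUE) {
  check_aligned(changemap, ai)
  ok <- !is.na(changemap$values) & !is.na(ai$values)
  n_excl <- sum(!is.na(changemap$values) & is.na(ai$values))
  y <- as.integer(changemap$values[ok] == CHANGE_CLASSES[["loss"]])
  x_raw <- ai$values[ok]
  if (sum(y) == 0L || sum(y) == length(y)) {
    stop("need at least one loss and one non-loss cell", call. = FALSE)
  }
  mu <- mean(x_raw); sdv <- stats::sd(x_raw)
  x <- if (standardize) (x_raw - mu) / sdv else x_raw
  fit <- suppressWarnings(
    stats::glm(y ~ x, family = stats::binomial()))
  if (!fit$converged) stop("logistic fit did not converge", call. = FALSE)
  beta <- unname(stats::coef(fit)["x"])
  se <- unname(sqrt(diag(stats::vcov(fit)))["x"])
  p <- 2 * stats::pnorm(-abs(beta / se))
  fitted_p <- stats::fitted(fit)
  separation <- any(fitted_p > 1 - 1e-10) && any(fitted_p < 1e-10)
  ll_model <- as.numeric(stats::logLik(fit))
  null_fit <- stats::glm(y ~ 1, family = stats::binomial())
  ll_null <- as.numeric(stats::logLik(null_fit))
  structure(
    list(beta = beta, se = se, p_value = p,
         odds_ratio = or_from_beta(beta),
         pseudo_r2_pct = 100 * (1 - ll_model / ll_null),
         auc = auc_rank(fitted_p, y),
         n_cells = length(y), n_loss = sum(y),
         n_excluded_undefined_ai = n_excl,
         standardization = c(mean = mu, sd = sdv),
         standardize = standardize,
         separation = separation),
    class = "loss_regression"
  )
}

#' @export
print.loss_regression <- function(x, ...) {
  ptxt <- if (x$p_value < 0.001) "<0.001" else sprintf("%.4f", x$p_value)
  cat(sprintf(
    "habitat-loss logistic regression (n = %d, loss cells = %d)\n",
    x$n_cells, x$n_loss))
  cat(sprintf("  beta = %.4f (se %.4f), p %s\n", x$beta, x$se, ptxt))
  cat(sprintf("  OR per one-SD increase in aridity = %.2f\n", x$odds_ratio))
  cat(sprintf("  McFadden pseudo-R2 = %.2f%%, AUC = %.3f\n",
              x$pseudo_r2_pct, x$auc))
  if (x$separation) cat("  warning: complete separation detected\n")
  invisible(x)
}

#' Odds ratio per one-SD increase in aridity
#'
#' The predictor is the aridity index, which falls as aridity rises, so the
#' loss odds ratio per one-SD *increase in aridity* is `exp(-beta)`.
#'
#' @param beta logistic coefficient on the standardized aridity index.
#' @return positive odds ratio.
#' @export
or_from_beta <- function(beta) {
  stopifnot(is.finite(beta))
  exp(-beta)
}
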