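#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from the ordinary
#' least-squares regression of variable `j` on all other variables (with
#' intercept). A perfectly collinear variable (R2 = 1 to numerical
#' precision) is reported as `Inf`.
#'
#' @param x numeric matrix or data.frame of candidate variables (columns).
#' @return named numeric vector of VIFs.
#' @export
compute_vif <- function(x) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (p < 2L) stop("need at least 2 variables to compute VIF", call. = FALSE)
  if (nrow(x) <= p + 1L) {
    stop("need more rows than variables + 1", call. = FALSE)
  }
  vif <- numeric(p)
  for (j in seq_len(p)) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    y <- x[, j]
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    r2 <- if (tss > 0) 1 - rss / tss else 1
    vif[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  names(vif) <- colnames(x)
  vif
}

#' Iterative VIF pruning
#'
#' Repeatedly removes the single variable with the largest VIF while any VIF
#' exceeds the threshold (ties broken by column order, first wins), then
#' reports per-variable VIF and tolerance (TOL = 1/VIF) for the retained
#' set plus the Pearson correlation matrix of the survivors.
#'
#' @param x numeric matrix/data.frame of candidate variables.
#' @param threshold VIF threshold (> 1); the conventional screening value
#'   is 5.
#' @return a `screen_report` list: `table` (data.frame `variable`, `vif`,
#'   `tol`, `retained`), `drop_order` (data.frame `variable`,
#'   `vif_at_drop`), `retained` (character), `pearson` (matrix).
#' @export
iterative_prune <- function(x, threshold = 5) {
  if (threshold <= 1) stop("threshold must exceed 1", call. = FALSE)
  x <- as.matrix(x)
  vars <- colnames(x)
  stopifnot(!is.null(vars))
  dropped <- character(0); drop_vif <- numeric(0)
  current <- vars
  repeat {
    if (length(current) < 2L) break
    v <- compute_vif(x[, current, drop = FALSE])
    worst <- which.max(v)          # first index wins on ties
    if (v[worst] <= threshold) break
    dropped <- c(dropped, current[worst])
    drop_vif <- c(drop_vif, v[worst])
    current <- current[-worst]
  }
  final_vif <- if (length(current) >= 2L) {
    compute_vif(x[, current, drop = FALSE])
  } else {
    stats::setNames(rep(1, length(current)), current)
  }
  tab <- data.frame(
    variable = vars,
    vif = ifelse(vars %in% current, final_vif[match(vars, current)], NA_real_),
    tol = NA_real_,
    retained = vars %in% current,
    stringsAsFactors = FALSE
  )
  tab$tol <- 1 / tab$vif
  structure(
    list(table = tab,
         drop_order = data.frame(variable = dropped, vif_at_drop = drop_vif,
                                 stringsAsFactors = FALSE),
         retained = current,
         pearson = pearson_matrix(x[, current, drop = FALSE])),
    class = "screen_report"
  )
}

#' Pearson correlation matrix with constant-column handling
#'
#' Standard product-moment correlations; a constant column has undefined
#' correlation, reported as 0 and flagged via the `constant_columns`
#' attribute.
#'
#' @param x numeric matrix/data.frame (>= 2 rows).
#' @return correlation matrix (diagonal 1) with attribute
#'   `constant_columns`.
#' @export
pearson_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows", call. = FALSE)
  const <- apply(x, 2L, function(v) stats::sd(v) == 0)
  m <- suppressWarnings(stats::cor(x))
  m[is.na(m)] <- 0
  diag(m) <- 1
  attr(m, "constant_columns") <- colnames(x)[const]
  m
}
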