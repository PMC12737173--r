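#' Stratified train/test replicate splits
#'
#' Builds `n_reps` independent 80/20 (by default) splits of a
#' presence/absence feature table, stratified by label so both classes
#' appear in every training and test set. The total training size is
#' `floor(train_frac * n)`, allocated per class by largest remainder.
#'
#' @param labels 0/1 vector (or a feature table data.frame with a `label`
#'   column).
#' @param n_reps number of replicates.
#' @param train_frac training fraction.
#' @param seed integer seed.
#' @return list of replicate splits, each a list with `replicate_id`,
#'   `train`, `test` (integer row indices).
#' @export
make_replicates <- function(labels, n_reps = 10, train_frac = 0.8, seed = 1L) {
  if (is.data.frame(labels)) labels <- labels$label
  n <- length(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L || any(table(labels) < 2L)) {
    stop("both classes need at least 2 members", call. = FALSE)
  }
  n_train <- floor(train_frac * n)
  exact <- train_frac * tabulate(factor(labels, classes))
  base <- floor(exact)
  rem <- n_train - sum(base)
  extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
  per_class <- base
  per_class[extra] <- per_class[extra] + 1L
  with_local_seed(seed, {
    lapply(seq_len(n_reps), function(rep_id) {
      train <- integer(0)
      for (k in seq_along(classes)) {
        rows_k <- which(labels == classes[k])
        train <- c(train, sample(rows_k, per_class[k]))
      }
      train <- sort(train)
      list(replicate_id = rep_id, train = train,
           test = setdiff(seq_len(n), train))
    })
  })
}

#' Fit one suitability algorithm
#'
#' Returns a fitted scorer mapping covariate vectors to scores in \[0, 1\].
#' Available algorithms:
#' * `glm` — logistic regression on standardized covariates;
#' * `rf` — random forest classifier (300 trees);
#' * `brt` — boosted regression trees (xgboost, 150 rounds, eta 0.1,
#'   depth 3);
#' * `svm` — RBF support vector machine with probability calibration;
#' * `bioclim` — presence-only percentile envelope: per variable
#'   `s_j = clip(1 - 2 * |F_j(x_j) - 0.5|, 0, 1)` with `F_j` the mid-rank
#'   empirical CDF of presence training values, score `min_j s_j`;
#' * `mahalanobis` — presence-only Mahalanobis distance `D2` to the presence
#'   mean with presence covariance (ridge-regularized by
#'   `1e-6 * trace/k` on the diagonal if singular), score
#'   `P(chisq_k > D2)`.
#'
#' @param name algorithm name (see above).
#' @param train feature table rows used for training: data.frame with
#'   `label` (0/1) and covariate columns.
#' @param vars character vector of covariate column names.
#' @param seed integer seed for stochastic fits.
#' @return an `sdm_scorer` object.
#' @export
fit_algorithm <- function(name, train, vars, seed = 1L) {
  name <- match.arg(name, SDM_ALGORITHMS)
  x <- as.matrix(train[, vars, drop = FALSE])
  y <- train$label
  fitted <- switch(
    name,
    glm = {
      mu <- colMeans(x); sdv <- apply(x, 2L, stats::sd)
      sdv[sdv == 0] <- 1
      xs <- scale(x, center = mu, scale = sdv)
      df <- data.frame(label = y, xs)
      fit <- suppressWarnings(
        stats::glm(label ~ ., data = df, family = stats::binomial()))
      list(fit = fit, center = mu, scale = sdv)
    },
    rf = with_local_seed(seed,
      randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                 ntree = 300)),
    brt = with_local_seed(seed,
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = 0.1,
                      max_depth = 3, nthread = 1),
        data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
        nrounds = 150, verbose = 0)),
    svm = with_local_seed(seed,
      e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
                 cost = 1, probability = TRUE)),
    bioclim = list(presence = x[y == 1, , drop = FALSE]),
    mahalanobis = {
      xp <- x[y == 1, , drop = FALSE]
      mu <- colMeans(xp)
      S <- stats::cov(xp)
      k <- ncol(xp)
      if (!is.finite(rcond(S)) || rcond(S) < 1e-12) {
        warning("singular presence covariance; ridge-regularizing",
                call. = FALSE)
        S <- S + diag(1e-6 * sum(diag(S)) / k, k)
      }
      list(mu = mu, Sinv = solve(S), k = k)
    }
  )
  structure(list(algorithm = name, vars = vars, fitted = fitted, seed = seed),
            class = "sdm_scorer")
}

#' @rdname fit_algorithm
#' @format NULL
#' @export
SDM_ALGORITHMS <- c("glm", "rf", "brt", "svm", "bioclim", "mahalanobis")

# mid-rank empirical CDF of v evaluated at x
midrank_cdf <- function(x, v) {
  n <- length(v)
  (vapply(x, function(xi) sum(v < xi), numeric(1)) +
     0.5 * vapply(x, function(xi) sum(v == xi), numeric(1))) / n
}

#' Score new data with a fitted scorer
#'
#' @param scorer an `sdm_scorer` from [fit_algorithm()].
#' @param newdata data.frame or matrix containing the scorer's covariate
#'   columns.
#' @return numeric vector of suitability scores in \[0, 1\].
#' @export
predict_scores <- function(scorer, newdata) {
  stopifnot(inherits(scorer, "sdm_scorer"))
  x <- as.matrix(as.data.frame(newdata)[, scorer$vars, drop = FALSE])
  f <- scorer$fitted
  switch(
    scorer$algorithm,
    glm = {
      xs <- scale(x, center = f$center, scale = f$scale)
      unname(stats::predict(f$fit, newdata = as.data.frame(xs),
                            type = "response"))
    },
    rf = unname(stats::predict(f, x, type = "prob")[, "1"]),
    brt = unname(stats::predict(f, xgboost::xgb.DMatrix(x, nthread = 1))),
    svm = {
      p <- stats::predict(f, x, probability = TRUE)
      unname(attr(p, "probabilities")[, "1"])
    },
    bioclim = {
      s <- vapply(seq_along(scorer$vars), function(j) {
        fx <- midrank_cdf(x[, j], f$presence[, j])
        pmin(pmax(1 - 2 * abs(fx - 0.5), 0), 1)
      }, numeric(nrow(x)))
      if (!is.matrix(s)) s <- matrix(s, nrow = nrow(x))
      apply(s, 1L, min)
    },
    mahalanobis = {
      d <- sweep(x, 2L, f$mu)
      d2 <- rowSums((d %*% f$Sinv) * d)
      stats::pchisq(d2, df = f$k, lower.tail = FALSE)
    }
  )
}

#' Rank-based AUC with tie correction
#'
#' Mann-Whitney formulation: the probability that a random presence scores
#' above a random absence, ties counting one half.
#'
#' @param scores numeric score vector.
#' @param labels 0/1 vector, same length.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Maximum-TSS threshold scan
#'
#' Scans every distinct score as a candidate threshold (prediction positive
#' iff `score >= t`) and returns the threshold maximizing the True Skill
#' Statistic `sensitivity + specificity - 1`; TSS ties resolve to the
#' smallest threshold.
#'
#' @param scores,labels as in [auc_rank()].
#' @return list with `tss`, `threshold`, `sensitivity`, `specificity`.
#' @export
max_tss <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("TSS needs both classes", call. = FALSE)
  thr <- sort(unique(scores))
  best <- list(tss = -Inf, threshold = NA_real_,
               sensitivity = NA_real_, specificity = NA_real_)
  for (t in thr) {
    pred <- scores >= t
    sens <- sum(pred & labels == 1) / n1
    spec <- sum(!pred & labels == 0) / n0
    tss <- sens + spec - 1
    if (tss > best$tss + 1e-15) {
      best <- list(tss = tss, threshold = t, sensitivity = sens,
                   specificity = spec)
    }
  }
  best
}

#' Evaluate a scorer on held-out rows
#'
#' @param scorer fitted `sdm_scorer`.
#' @param test feature-table rows with `label` and covariates.
#' @param replicate_id replicate identifier carried into the record.
#' @return one-row data.frame: `algorithm`, `replicate`, `auc`, `tss`,
#'   `threshold`, `sensitivity`, `specificity`.
#' @export
evaluate_scorer <- function(scorer, test, replicate_id = NA_integer_) {
  if (length(unique(test$label)) < 2L) {
    stop("test set has a single class; cannot evaluate", call. = FALSE)
  }
  s <- predict_scores(scorer, test)
  ts <- max_tss(s, test$label)
  data.frame(algorithm = scorer$algorithm, replicate = replicate_id,
             auc = auc_rank(s, test$label), tss = ts$tss,
             threshold = ts$threshold, sensitivity = ts$sensitivity,
             specificity = ts$specificity, stringsAsFactors = FALSE)
}

#' Fit and evaluate all algorithms over all replicates
#'
#' @param table feature table with `label` and covariate columns.
#' @param vars covariate column names.
#' @param algorithms algorithm names (subset of `SDM_ALGORITHMS`).
#' @param n_reps,train_frac,seed replicate design (see [make_replicates()]).
#' @return list: `evals` (data.frame of per-algorithm, per-replicate
#'   records), `scorers` (named list `algorithm` -> list of per-replicate
#'   scorers), `splits`.
#' @export
fit_all <- function(table, vars, algorithms = SDM_ALGORITHMS, n_reps = 10,
                    train_frac = 0.8, seed = 1L) {
  if (length(algorithms) == 0L) stop("empty algorithm list", call. = FALSE)
  splits <- make_replicates(table$label, n_reps = n_reps,
                            train_frac = train_frac, seed = seed)
  evals <- list(); scorers <- list()
  for (alg in algorithms) {
    scorers[[alg]] <- vector("list", length(splits))
    for (sp in splits) {
      sc <- fit_algorithm(alg, table[sp$train, , drop = FALSE], vars,
                          seed = seed + sp$replicate_id)
      sc$replicate_id <- sp$replicate_id
      scorers[[alg]][[sp$replicate_id]] <- sc
      evals[[length(evals) + 1L]] <-
        evaluate_scorer(sc, table[sp$test, , drop = FALSE],
                        replicate_id = sp$replicate_id)
    }
  }
  list(evals = do.call(rbind, evals), scorers = scorers, splits = splits)
}

#' Gate algorithms on mean AUC and mean TSS
#'
#' Algorithm-level gating: an algorithm is kept iff its mean AUC and mean
#' TSS across replicates meet both thresholds.
#'
#' @param evals evaluation data.frame from [fit_all()]/[evaluate_scorer()].
#' @param auc_min,tss_min gating thresholds.
#' @param error_if_empty stop with a per-algorithm report when nothing
#'   passes (default `TRUE`).
#' @return data.frame: `algorithm`, `mean_auc`, `mean_tss`, `kept`.
#' @export
gate <- function(evals, auc_min = 0.9, tss_min = 0.7, error_if_empty = TRUE) {
  stopifnot(nrow(evals) >= 1L)
  agg <- stats::aggregate(cbind(auc, tss) ~ algorithm, data = evals, FUN = mean)
  names(agg) <- c("algorithm", "mean_auc", "mean_tss")
  agg$kept <- agg$mean_auc >= auc_min & agg$mean_tss >= tss_min
  if (error_if_empty && !any(agg$kept)) {
    stop("empty ensemble: no algorithm passed AUC >= ", auc_min,
         " and TSS >= ", tss_min, "\n",
         paste(sprintf("  %s: AUC %.3f, TSS %.3f", agg$algorithm,
                       agg$mean_auc, agg$mean_tss), collapse = "\n"),
         call. = FALSE)
  }
  agg
}

#' Permutation variable importance for one scorer
#'
#' `contribution_j = max(0, 1 - cor(original scores, scores with column j
#' permuted))`, averaged over `n_perm` permutations. Constant original
#' scores give all-zero contributions (flagged by attribute).
#'
#' @param scorer fitted `sdm_scorer`.
#' @param data rows to permute over (feature table with covariates).
#' @param n_perm permutations per variable.
#' @param seed integer seed.
#' @return named numeric vector of contributions in \[0, 1\].
#' @export
variable_importance <- function(scorer, data, n_perm = 10, seed = 1L) {
  x <- as.data.frame(data)[, scorer$vars, drop = FALSE]
  s0 <- predict_scores(scorer, x)
  out <- stats::setNames(numeric(length(scorer$vars)), scorer$vars)
  if (stats::sd(s0) == 0) {
    attr(out, "constant_scores") <- TRUE
    return(out)
  }
  with_local_seed(seed, {
    for (j in seq_along(scorer$vars)) {
      vals <- numeric(n_perm)
      for (p in seq_len(n_perm)) {
        xp <- x
        xp[[j]] <- xp[[j]][sample.int(nrow(xp))]
        sp <- predict_scores(scorer, xp)
        r <- if (stats::sd(sp) == 0) 0 else stats::cor(s0, sp)
        vals[p] <- max(0, 1 - r)
      }
      out[j] <- mean(vals)
    }
  })
  out
}

#' Cross-algorithm importance table
#'
#' @param scorers named list `algorithm` -> list of per-replicate scorers
#'   (from [fit_all()]), restricted to kept algorithms.
#' @param data feature table rows to evaluate importance on.
#' @param n_perm,seed passed to [variable_importance()].
#' @return data.frame: one row per variable, one column per algorithm plus
#'   `mean`, contributions averaged over replicates.
#' @export
importance_table <- function(scorers, data, n_perm = 10, seed = 1L) {
  algs <- names(scorers)
  vars <- scorers[[1L]][[1L]]$vars
  cols <- lapply(algs, function(a) {
    reps <- vapply(seq_along(scorers[[a]]), function(i) {
      variable_importance(scorers[[a]][[i]], data, n_perm = n_perm,
                          seed = seed + i)
    }, numeric(length(vars)))
    rowMeans(matrix(reps, nrow = length(vars)))
  })
  tab <- data.frame(variable = vars, stringsAsFactors = FALSE)
  for (k in seq_along(algs)) tab[[algs[k]]] <- cols[[k]]
  tab$mean <- rowMeans(as.matrix(tab[, algs, drop = FALSE]))
  tab[order(-tab$mean), ]
}

#' Ensemble prediction over a raster stack
#'
#' Per-cell combination of all kept scorers' outputs: unweighted mean by
#' default, or a TSS-weighted mean (`weight = max(0, tss)`). Nodata cells
#' propagate.
#'
#' @param scorers flat list of `sdm_scorer`s to combine.
#' @param stack named list of aligned `raster_grid`s containing every
#'   covariate layer.
#' @param weights optional numeric vector parallel to `scorers` (e.g. TSS
#'   values); negative weights are clamped to 0.
#' @return probability `raster_grid` in \[0, 1\].
#' @export
ensemble_predict <- function(scorers, stack, weights = NULL) {
  if (length(scorers) == 0L) stop("empty ensemble", call. = FALSE)
  sm <- stack_matrix(stack)
  preds <- vapply(scorers, function(sc) predict_scores(sc, sm$x),
                  numeric(nrow(sm$x)))
  if (!is.matrix(preds)) preds <- matrix(preds, ncol = length(scorers))
  if (is.null(weights)) {
    v <- rowMeans(preds)
  } else {
    stopifnot(length(weights) == length(scorers))
    w <- pmax(0, weights)
    if (sum(w) == 0) stop("all ensemble weights are zero", call. = FALSE)
    v <- drop(preds %*% w) / sum(w)
  }
  raster_from_cells(sm$template, sm$cells, v)
}
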