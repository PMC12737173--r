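# brute-force AUC: pairwise presence/absence comparisons, ties half credit
auc_oracle <- function(scores, labels) {
  sp <- scores[labels == 1]; sa <- scores[labels == 0]
  tot <- 0
  for (i in seq_along(sp)) {
    tot <- tot + sum(sp[i] > sa) + 0.5 * sum(sp[i] == sa)
  }
  tot / (length(sp) * length(sa))
}

# exhaustive TSS scan oracle
tss_oracle <- function(scores, labels) {
  best <- -Inf; best_t <- NA
  for (t in sort(unique(scores))) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    tss <- sens + spec - 1
    if (tss > best + 1e-15) { best <- tss; best_t <- t }
  }
  list(tss = best, threshold = best_t)
}

test_that("replicate splits partition rows and stratify by label", {
  labels <- c(rep(1, 60), rep(0, 40))
  splits <- make_replicates(labels, n_reps = 10, train_frac = 0.8, seed = 3)
  expect_length(splits, 10)
  for (sp in splits) {
    expect_length(sp$test, 20)
    expect_setequal(c(sp$train, sp$test), 1:100)
    expect_length(intersect(sp$train, sp$test), 0)
    # stratification: train class counts within 1 of the global 80% ratio
    expect_lte(abs(sum(labels[sp$train]) - 48), 1)
  }
  expect_error(make_replicates(c(1, 1, 1, 0), seed = 1), "2 members")
})

test_that("bioclim envelope scores 1 at the presence median, 0 outside", {
  set.seed(4)
  train <- data.frame(label = rep(1, 31), v1 = rnorm(31), v2 = rnorm(31))
  sc <- fit_algorithm("bioclim", train, c("v1", "v2"))
  center <- data.frame(v1 = median(train$v1), v2 = median(train$v2))
  expect_equal(predict_scores(sc, center), 1)
  outside <- data.frame(v1 = max(train$v1) + 1, v2 = 0)
  expect_equal(predict_scores(sc, outside), 0)
})

test_that("mahalanobis scorer is 1 at the presence mean and falls outward", {
  set.seed(5)
  train <- data.frame(label = rep(1, 40), v1 = rnorm(40), v2 = rnorm(40))
  sc <- fit_algorithm("mahalanobis", train, c("v1", "v2"))
  at_mean <- data.frame(v1 = mean(train$v1), v2 = mean(train$v2))
  expect_equal(predict_scores(sc, at_mean), 1)
  away <- data.frame(v1 = mean(train$v1) + 10, v2 = mean(train$v2))
  expect_lt(predict_scores(sc, away), 0.01)
})

test_that("singular presence covariance triggers ridge regularization", {
  train <- data.frame(label = rep(1, 20), v1 = 1:20, v2 = 2 * (1:20))
  expect_warning(sc <- fit_algorithm("mahalanobis", train, c("v1", "v2")),
                 "ridge")
  expect_true(all(is.finite(predict_scores(sc, train))))
})

test_that("perfect separation gives AUC 1 and TSS 1; constant scores give 0.5 and 0", {
  labels <- c(rep(0, 10), rep(1, 10))
  scores <- c(runif(10, 0, 0.4), runif(10, 0.6, 1))
  expect_equal(auc_rank(scores, labels), 1)
  expect_equal(max_tss(scores, labels)$tss, 1)
  flat <- rep(0.3, 20)
  expect_equal(auc_rank(flat, labels), 0.5)
  expect_equal(max_tss(flat, labels)$tss, 0)
})

test_that("AUC and max-TSS match brute-force oracles on random sets", {
  set.seed(6)
  for (i in 1:50) {
    n <- sample(10:50, 1)
    scores <- round(runif(n), 2)       # rounding forces ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(auc_rank(scores, labels), auc_oracle(scores, labels),
                 tolerance = 1e-12)
    got <- max_tss(scores, labels)
    want <- tss_oracle(scores, labels)
    expect_equal(got$tss, want$tss, tolerance = 1e-12)
    expect_equal(got$threshold, want$threshold)
    # stored TSS equals sensitivity + specificity - 1 exactly
    expect_identical(got$tss, got$sensitivity + got$specificity - 1)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(7)
  scores <- runif(40); labels <- rbinom(40, 1, 0.5)
  labels[1] <- 1; labels[2] <- 0
  a0 <- auc_rank(scores, labels)
  expect_equal(auc_rank(exp(3 * scores), labels), a0, tolerance = 1e-12)
  expect_equal(auc_rank(rank(scores), labels), a0, tolerance = 1e-12)
})

test_that("gating keeps exactly the algorithms passing both thresholds", {
  evals <- data.frame(
    algorithm = rep(c("a", "b", "c"), each = 2),
    replicate = rep(1:2, 3),
    auc = c(0.89, 0.89, 0.91, 0.91, 0.95, 0.95),
    tss = c(0.80, 0.80, 0.71, 0.71, 0.65, 0.65))
  g <- gate(evals, auc_min = 0.9, tss_min = 0.7)
  expect_equal(g$kept, c(FALSE, TRUE, FALSE))   # a fails AUC, c fails TSS
  g2 <- gate(evals, auc_min = 0, tss_min = -1)
  expect_true(all(g2$kept))
  expect_error(gate(evals, auc_min = 0.99, tss_min = 0.99), "empty ensemble")
})

test_that("glm scorer recovers truth signs and evaluation is coherent", {
  tab <- random_feature_table(n = 2000, seed = 8)
  splits <- make_replicates(tab$label, n_reps = 2, seed = 9)
  sc <- fit_algorithm("glm", tab[splits[[1]]$train, ], paste0("v", 1:4))
  co <- coef(sc$fitted$fit)
  expect_gt(co["v1"], 0); expect_lt(co["v2"], 0)
  ev <- evaluate_scorer(sc, tab[splits[[1]]$test, ], replicate_id = 1)
  expect_gt(ev$auc, 0.8)
  expect_equal(ev$tss, ev$sensitivity + ev$specificity - 1)
})

test_that("permutation importance isolates the informative variable", {
  set.seed(10)
  n <- 600
  tab <- data.frame(label = NA, v1 = rnorm(n), v2 = rnorm(n), v3 = rnorm(n))
  tab$label <- rbinom(n, 1, plogis(3 * tab$v1))
  sc <- fit_algorithm("glm", tab, c("v1", "v2", "v3"))
  imp <- variable_importance(sc, tab, n_perm = 5, seed = 11)
  expect_equal(which.max(imp), c(v1 = 1))
  expect_lte(imp["v2"], 0.02)
  expect_lte(imp["v3"], 0.02)
})

test_that("ensemble_predict averages member rasters and stays bounded", {
  lay <- tiny_layers(tiny_world(seed = 23))
  tm <- truth_model(c(elevation = -0.02, bio19 = 0.15),
                    intercept = 0.02 * 700 - 0.15 * 335 - 2)
  occ <- sample_occurrences(tm, lay, 120, seed = 1)
  mask <- flat_raster(1, 24, 32, cellsize = 10)
  ab <- generate_pseudo_absences(mask, 120, min_dist_km = 0, seed = 2)
  tab <- build_feature_table(occ, ab, lay)
  vars <- c("elevation", "bio19", "bio4")
  s1 <- fit_algorithm("glm", tab, vars, seed = 1)
  s2 <- fit_algorithm("bioclim", tab, vars, seed = 1)
  e1 <- ensemble_predict(list(s1), lay)
  e12 <- ensemble_predict(list(s1, s2), lay)
  p1 <- predict_scores(s1, stack_matrix(lay)$x)
  p2 <- predict_scores(s2, stack_matrix(lay)$x)
  # single member: ensemble equals that member
  expect_equal(as.vector(e1$values), p1, tolerance = 1e-12)
  # mean of members, bounded by members
  expect_equal(as.vector(e12$values), (p1 + p2) / 2, tolerance = 1e-12)
  expect_true(all(e12$values >= pmin(p1, p2) - 1e-12 &
                    e12$values <= pmax(p1, p2) + 1e-12))
  # TSS-weighted combination
  ew <- ensemble_predict(list(s1, s2), lay, weights = c(0.8, 0.4))
  expect_equal(as.vector(ew$values), (0.8 * p1 + 0.4 * p2) / 1.2,
               tolerance = 1e-12)
  expect_error(ensemble_predict(list(), lay), "empty")
})

test_that("all six algorithms emit calibrated scores in [0, 1]", {
  tab <- random_feature_table(n = 300, seed = 12)
  vars <- paste0("v", 1:4)
  for (alg in SDM_ALGORITHMS) {
    sc <- fit_algorithm(alg, tab, vars, seed = 13)
    s <- predict_scores(sc, tab)
    expect_true(all(s >= 0 & s <= 1), info = alg)
    expect_gt(auc_rank(s, tab$label), 0.6)
  }
})
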