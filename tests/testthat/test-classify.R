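# two linearly separated feature clouds for sanity runs
separable_data <- function(n = 120, seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), each = n / 2)
  x <- data.frame(a = rnorm(n) + 3 * y, b = rnorm(n))
  list(x = x, y = y)
}

test_that("stratified 75/25 partition reproduces the study's split sizes", {
  y <- rep(c(1, 0), c(143, 215))  # the genus-E label distribution, n = 358
  p <- partition(y, 0.75, seed = 5)
  expect_equal(length(p$test), 88L)
  expect_equal(length(p$train), 270L)
  # class proportions preserved within one observation
  expect_equal(sum(y[p$train]), 108)
  expect_equal(sum(y[p$test]), 35)
  # a partition is a partition
  expect_setequal(c(p$train, p$test), seq_along(y))
  expect_identical(p, partition(y, 0.75, seed = 5))
  expect_false(identical(p$train, partition(y, 0.75, seed = 6)$train))
  expect_error(partition(rep(1, 10)), "each class")
})

test_that("metric formulas reproduce held-out confusion matrices exactly", {
  # n = 88 matrices consistent with the published fused- and RS-model tables
  m1 <- classification_metrics(c(TP = 30, FP = 3, TN = 50, FN = 5))
  expect_equal(round(unname(m1), 3), c(0.857, 0.943, 0.909, 0.882, 0.909))
  m2 <- classification_metrics(c(TP = 21, FP = 8, TN = 48, FN = 11))
  expect_equal(round(unname(m2), 3), c(0.656, 0.857, 0.724, 0.689, 0.784))
  m3 <- classification_metrics(c(TP = 25, FP = 15, TN = 38, FN = 10))
  expect_equal(round(unname(m3), 3), c(0.714, 0.717, 0.625, 0.667, 0.716))
  # zero denominators are undefined, not zero
  none <- classification_metrics(c(TP = 0, FP = 0, TN = 10, FN = 0))
  expect_true(is.na(none[["sensitivity"]]))
  expect_true(is.na(none[["precision"]]))
  expect_equal(none[["accuracy"]], 1)
  # internal consistency on random matrices
  set.seed(2)
  for (i in 1:20) {
    cm <- c(TP = rpois(1, 20) + 1, FP = rpois(1, 5), TN = rpois(1, 30) + 1,
            FN = rpois(1, 5))
    m <- classification_metrics(cm)
    expect_equal(m[["accuracy"]], (cm[["TP"]] + cm[["TN"]]) / sum(cm))
    if (!is.na(m[["f1"]]))
      expect_equal(m[["f1"]], 2 / (1 / m[["precision"]] + 1 / m[["sensitivity"]]))
  }
})

test_that("confusion counts come from predicted x observed cross-tabulation", {
  cm <- confusion(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1))
  expect_equal(unclass(cm), c(TP = 2L, FP = 1L, TN = 1L, FN = 1L))
})

test_that("rank-based AUC agrees with ROC integration and handles ties", {
  expect_equal(auc_mw(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_mw(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_true(is.na(auc_mw(1:5, rep(1, 5))))
  set.seed(7)
  for (i in 1:50) {
    n <- sample(20:80, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(n, y), sample(c(1, 2, 8), 1))  # induce ties sometimes
    expect_equal(auc_mw(s, y), auc_trapezoid(s, y), tolerance = 1e-12)
  }
  # second independent route
  y <- rbinom(100, 1, 0.5); s <- rnorm(100, y)
  expect_equal(auc_mw(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("repeated stratified folds cover each repeat exactly once", {
  y <- rep(c(0, 1), c(60, 40))
  folds <- cv_folds(y, k = 10, repeats = 3, seed = 2)
  expect_length(folds, 30L)
  for (r in 1:3) {
    held <- unlist(lapply(folds[sapply(folds, `[[`, "repeat_id") == r],
                          `[[`, "test"))
    expect_setequal(held, seq_along(y))
  }
  # stratification: each held-out fold keeps both classes
  for (f in folds) expect_length(unique(y[f$test]), 2L)
})

test_that("AUC-based tuning separates signal from a permutation null", {
  d <- separable_data(n = 120, seed = 3)
  for (learner in c("gbm", "rf", "svm")) {
    grid <- switch(learner,
      gbm = data.frame(n.trees = 100L, interaction.depth = 2L),
      rf = data.frame(mtry = 1L),
      svm = data.frame(sigma = 0.5, C = 1))
    m <- train_tuned(d$x, d$y, learner, grid = grid, k = 5, repeats = 2,
                     seed = 4)
    expect_gt(m$cv_auc, 0.95)
    expect_equal(m$best_params, grid)   # singleton grid is always selected
    expect_true(all(m$cv_records$prob >= 0 & m$cv_records$prob <= 1))
  }
  # permuted labels: no learnable structure
  set.seed(9)
  y_perm <- sample(d$y)
  m0 <- train_tuned(d$x, y_perm, "rf", grid = data.frame(mtry = 1L),
                    k = 5, repeats = 2, seed = 4)
  expect_gt(m0$cv_auc, 0.35)
  expect_lt(m0$cv_auc, 0.65)
})

test_that("the tuner picks the AUC-maximizing grid point", {
  d <- separable_data(n = 120, seed = 5)
  grid <- data.frame(n.trees = c(10L, 150L), interaction.depth = c(1L, 2L))
  m <- train_tuned(d$x, d$y, "gbm", grid = grid, k = 5, repeats = 2, seed = 6)
  expect_equal(nrow(m$grid), 2L)
  expect_equal(m$best_params$n.trees,
               m$grid$n.trees[which.max(m$grid$cv_auc)])
  expect_equal(m$cv_auc, max(m$grid$cv_auc))
  # CV AUC SD is the sample SD over the resample AUCs
  recs <- split(m$cv_records, m$cv_records$resample)
  aucs <- vapply(recs, function(r) auc_mw(r$prob, r$obs), 0)
  expect_equal(m$cv_auc_sd, sd(aucs))
  expect_length(aucs, 10L)  # 5 folds x 2 repeats
})

test_that("importance ranks generative predictors above pure noise", {
  hits <- 0L
  for (s in 1:10) {
    set.seed(s)
    n <- 150
    signal <- rnorm(n)
    x <- data.frame(signal = signal, noise = rnorm(n))
    y <- rbinom(n, 1, plogis(2.5 * signal))
    if (length(unique(y)) < 2) next
    m <- train_tuned(x, y, "rf", grid = data.frame(mtry = 1L),
                     k = 5, repeats = 1, seed = s)
    imp <- importance_scaled(m)
    if (imp$variable[1] == "signal") hits <- hits + 1L
    expect_equal(max(imp$importance), 100)
    expect_equal(min(imp$importance), 0)
  }
  expect_gte(hits, 9L)
  # single predictor sits at the scale ceiling
  d <- separable_data(80, seed = 2)
  m1 <- train_tuned(d$x["a"], d$y, "rf", grid = data.frame(mtry = 1L),
                    k = 5, repeats = 1, seed = 3)
  expect_equal(importance_scaled(m1)$importance, 100)
})

test_that("partial dependence recovers shape and ignores unused variables", {
  set.seed(12)
  n <- 300
  x <- data.frame(u = runif(n, -3, 3), v = runif(n, -3, 3))
  y <- rbinom(n, 1, plogis(2 * x$u))
  m <- train_tuned(x, y, "gbm",
                   grid = data.frame(n.trees = 200L, interaction.depth = 2L),
                   k = 5, repeats = 1, seed = 13)
  pd_u <- partial_dependence(m, "u", n_points = 15)
  expect_true(all(pd_u$yhat >= 0 & pd_u$yhat <= 1))
  # recovers the logistic shape: tightly rank-correlated and wide in range
  expect_gt(cor(pd_u$yhat, plogis(2 * pd_u$value), method = "spearman"), 0.95)
  expect_gt(diff(range(pd_u$yhat)), 0.5)
  pd_v <- partial_dependence(m, "v", n_points = 15)
  # near-flat for the inert variable, relative to the generative one
  expect_lt(diff(range(pd_v$yhat)), 0.25 * diff(range(pd_u$yhat)))
  expect_error(partial_dependence(m, "w"), "unknown variable")
})

test_that("fused field + remote-sensing models beat remote sensing alone", {
  # the generator routes part of the occupancy signal exclusively through
  # the plot community (richness suppression on invaded plots), so the
  # fused feature set must carry strictly more information
  ts <- get_test_scene()
  ff <- field_features(ts$scene$plots, nmds_restarts = 3, seed = 1)
  rs <- rs_features(ts$layers, ts$scene$plots$plots[, c("x", "y")])
  rs$x <- NULL; rs$y <- NULL
  fused <- cbind(ff$features[, fd_variable_names()], rs)
  y <- ts$scene$plots$plots$genusE_present
  idx <- partition(y, seed = 2)
  grid <- data.frame(n.trees = 100L, interaction.depth = 2L)
  m_fused <- train_tuned(fused[idx$train, ], y[idx$train], "gbm",
                         grid = grid, k = 5, repeats = 2, seed = 3)
  m_rs <- train_tuned(rs[idx$train, ], y[idx$train], "gbm",
                      grid = grid, k = 5, repeats = 2, seed = 3)
  expect_gt(m_fused$cv_auc, m_rs$cv_auc)
  expect_gt(m_rs$cv_auc, 0.5)  # the landscape itself is learnable
})

test_that("evaluation is order-invariant and threshold-sensible", {
  d <- separable_data(n = 160, seed = 21)
  idx <- partition(d$y, seed = 22)
  m <- train_tuned(d$x[idx$train, ], d$y[idx$train], "rf",
                   grid = data.frame(mtry = 1L), k = 5, repeats = 1,
                   seed = 23)
  ev <- evaluate_model(m, d$x[idx$test, ], d$y[idx$test])
  perm <- sample(length(idx$test))
  ev_p <- evaluate_model(m, d$x[idx$test, ][perm, ], d$y[idx$test][perm])
  expect_equal(ev$metrics, ev_p$metrics)
  expect_equal(ev$confusion, ev_p$confusion)
  expect_equal(ev$auc_sd, m$cv_auc_sd)
  # a degenerate all-negative rule has zero sensitivity
  ev0 <- evaluate_model(m, d$x[idx$test, ], d$y[idx$test], threshold = 1.01)
  expect_equal(ev0$metrics[["sensitivity"]], 0)
})
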