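## label utilities: presence-absence as a factor with "present" the positive
## class throughout the module
as_label <- function(y) {
  if (is.factor(y) || is.character(y)) {
    y <- as.character(y)
    if (!all(y %in% c("absent", "present")))
      stop("labels must be 'present'/'absent' or coercible to 0/1")
    return(factor(y, c("absent", "present")))
  }
  factor(ifelse(as.numeric(y) > 0, "present", "absent"),
         c("absent", "present"))
}

#' Stratified train/test partition
#'
#' Splits observations into training and testing sets preserving the class
#' balance: for each class, `ceiling(train_frac * n_class)` observations go
#' to training (so a 75/25 split of 358 observations with 143 presences
#' yields a test set of 88). Deterministic under the seed.
#'
#' @param labels presence-absence labels (0/1, logical or factor).
#' @param train_frac fraction of observations for training (default 0.75).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
partition <- function(labels, train_frac = 0.75, seed = 1L) {
  y <- as_label(labels)
  if (any(table(y) < 2L))
    stop("each class needs at least 2 observations to stratify")
  with_seed(seed, {
    train <- unlist(lapply(levels(y), function(lv) {
      idx <- which(y == lv)
      sample(idx, ceiling(train_frac * length(idx)))
    }), use.names = FALSE)
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(y), train))
  })
}

## stratified fold ids for one repeat; folds as equal as possible per class
fold_ids <- function(y, k, seed) {
  with_seed(seed, {
    f <- integer(length(y))
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      f[idx] <- rep_len(sample(k), length(idx))
    }
    f
  })
}

#' Repeated stratified cross-validation folds
#'
#' Builds `k` stratified folds, repeated `repeats` times, as a list of
#' resamples each holding the training and held-out row indices. Folds whose
#' held-out part would be single-class are regenerated under a new sub-seed
#' (with a warning); this can only trigger when a class has fewer members
#' than folds.
#'
#' @inheritParams partition
#' @param k folds per repeat (default 10).
#' @param repeats repeats (default 10).
#' @return list of `k * repeats` lists with elements `train`, `test`,
#'   `repeat_id`, `fold`.
#' @export
cv_folds <- function(labels, k = 10L, repeats = 10L, seed = 1L) {
  y <- as_label(labels)
  out <- vector("list", k * repeats)
  pos <- 0L
  for (r in seq_len(repeats)) {
    s <- sub_seed(seed, 100L + r)
    for (attempt in 1:100) {
      f <- fold_ids(y, k, s)
      ok <- all(vapply(seq_len(k), function(i)
        length(unique(y[f == i])) == 2L, TRUE))
      if (ok) break
      warning("single-class fold regenerated with a new sub-seed")
      s <- s + 7919
    }
    for (i in seq_len(k)) {
      pos <- pos + 1L
      out[[pos]] <- list(train = which(f != i), test = which(f == i),
                         repeat_id = r, fold = i)
    }
  }
  out
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Area under the ROC curve computed from the rank statistic with midrank
#' tie correction; equals the probability that a random positive outscores a
#' random negative (+ half the tie probability). `NA` when one class is
#' absent.
#'
#' @param scores numeric classifier scores or probabilities.
#' @param labels presence-absence labels.
#' @return AUC in \[0, 1\], or `NA`.
#' @export
auc_mw <- function(scores, labels) {
  y <- as_label(labels) == "present"
  keep <- !is.na(scores)
  y <- y[keep]; scores <- scores[keep]
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion matrix from predicted and observed presence-absence
#'
#' @param predicted,observed presence-absence labels of equal length.
#' @return named integer vector `c(TP, FP, TN, FN)` of class
#'   `confusion_matrix`.
#' @export
confusion <- function(predicted, observed) {
  p <- as_label(predicted) == "present"
  o <- as_label(observed) == "present"
  structure(c(TP = sum(p & o), FP = sum(p & !o),
              TN = sum(!p & !o), FN = sum(!p & o)),
            class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' Computes sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision
#' TP/(TP+FP), F1 (harmonic mean of precision and sensitivity) and accuracy
#' (TP+TN)/total. A metric whose denominator is zero is reported as `NA`
#' (undefined, distinct from 0).
#'
#' @param cm a [confusion()] result or named vector with TP, FP, TN, FN.
#' @return named numeric vector with the five metrics.
#' @export
classification_metrics <- function(cm) {
  cm <- unclass(cm)
  tp <- cm[["TP"]]; fp <- cm[["FP"]]; tn <- cm[["TN"]]; fn <- cm[["FN"]]
  total <- tp + fp + tn + fn
  if (total <= 0) stop("empty confusion matrix")
  safe_div <- function(a, b) if (b > 0) a / b else NA_real_
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  f1 <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  c(sensitivity = sens, specificity = spec, precision = prec,
    f1 = f1, accuracy = (tp + tn) / total)
}

## ----- learner engines ------------------------------------------------------

#' Default hyperparameter tuning grids
#'
#' Grids searched by AUC under repeated cross-validation. The gradient
#' booster varies the number of trees and interaction depth with the
#' learning rate fixed at 0.1 and the minimum node size at 20; the random
#' forest varies `mtry`; the radial SVM crosses a median-heuristic sigma
#' band (from [kernlab::sigest()]) with a cost ladder.
#'
#' @param learner `"gbm"`, `"rf"` or `"svm"`.
#' @param x training predictor matrix/data frame (needed for `rf` and
#'   `svm`).
#' @param seed integer seed (sigma heuristic only).
#' @return data frame, one row per candidate.
#' @export
default_tune_grid <- function(learner = c("gbm", "rf", "svm"), x = NULL,
                              seed = 1L) {
  learner <- match.arg(learner)
  switch(learner,
    gbm = expand.grid(n.trees = seq(50L, 500L, 50L),
                      interaction.depth = 1:3),
    rf = {
      p <- ncol(x)
      data.frame(mtry = unique(pmax(1L, floor(seq(1, p, length.out = 5)))))
    },
    svm = {
      sig <- with_seed(seed,
        kernlab::sigest(as.matrix(x), scaled = TRUE, frac = 1))
      expand.grid(sigma = unname(sig[c(1, 2, 3)]),
                  C = c(0.25, 0.5, 1, 2, 4))
    })
}

fit_learner <- function(learner, x, y, params, seed = 1L) {
  x <- as.matrix(x)
  y <- as_label(y)
  fit <- switch(learner,
    ## stochastic gradient boosting: learning rate fixed at 0.1, minimum
    ## terminal-node size fixed at 20 observations (~ hessian weight 5 under
    ## the logistic loss), half-sampling per iteration
    gbm = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$interaction.depth,
                    eta = 0.1, min_child_weight = 5, subsample = 0.5,
                    nthread = 1, seed = as.integer(seed %% 2147483647)),
      data = xgboost::xgb.DMatrix(x, label = as.integer(y == "present")),
      nrounds = params$n.trees, verbose = 0),
    rf = with_seed(seed, randomForest::randomForest(
      x = x, y = y, ntree = 500,
      mtry = min(params$mtry, ncol(x)))),
    svm = with_seed(seed, kernlab::ksvm(
      x = x, y = y, kernel = "rbfdot",
      kpar = list(sigma = params$sigma), C = params$C,
      prob.model = TRUE, scaled = TRUE)),
    stop("unknown learner: ", learner))
  list(learner = learner, fit = fit, features = colnames(x))
}

predict_prob <- function(engine, newx) {
  newx <- as.matrix(newx[, engine$features, drop = FALSE])
  switch(engine$learner,
    gbm = as.numeric(stats::predict(engine$fit,
                                    xgboost::xgb.DMatrix(newx))),
    rf = unname(stats::predict(engine$fit, newx,
                               type = "prob")[, "present"]),
    svm = unname(kernlab::predict(engine$fit, newx,
                                  type = "probabilities")[, "present"]))
}

## ----- tuning loop ----------------------------------------------------------

#' Train a tuned presence-absence classifier
#'
#' Grid search by mean held-out AUC under repeated stratified
#' cross-validation (10 folds x 10 repeats by default, the same folds for
#' every candidate), then a refit on all training rows at the AUC-maximizing
#' candidate. The held-out probability predictions, per-resample AUCs and
#' the AUC standard deviation over the resamples are retained for the chosen
#' candidate (they feed threshold selection and the reported AUC +- SD).
#'
#' @param x predictor data frame or matrix (numeric, no missing values).
#' @param y presence-absence labels.
#' @param learner `"gbm"` (gradient boosting), `"rf"` (random forest) or
#'   `"svm"` (radial-kernel SVM with Platt-type probability calibration).
#' @param grid tuning grid data frame; `NULL` for [default_tune_grid()].
#' @param k,repeats cross-validation geometry.
#' @param seed experiment seed governing folds and learner randomness by
#'   fixed sub-seeding.
#' @return object of class `trained_model`: chosen parameters, grid results,
#'   CV records (`resample`, `row`, `obs`, `prob`), `cv_auc`, `cv_auc_sd`,
#'   the refitted engine and the training data.
#' @export
train_tuned <- function(x, y, learner = c("gbm", "rf", "svm"), grid = NULL,
                        k = 10L, repeats = 10L, seed = 1L) {
  learner <- match.arg(learner)
  x <- as.data.frame(x)
  stopifnot(!anyNA(x))
  y <- as_label(y)
  if (is.null(grid)) grid <- default_tune_grid(learner, x, seed = seed)
  folds <- cv_folds(y, k = k, repeats = repeats,
                    seed = sub_seed(seed, 11L))

  eval_candidate <- function(params) {
    recs <- lapply(seq_along(folds), function(i) {
      fo <- folds[[i]]
      eng <- fit_learner(learner, x[fo$train, , drop = FALSE], y[fo$train],
                         params, seed = sub_seed(seed, 200L + i))
      prob <- predict_prob(eng, x[fo$test, , drop = FALSE])
      data.frame(resample = i, row = fo$test,
                 obs = as.character(y[fo$test]), prob = prob)
    })
    do.call(rbind, recs)
  }

  resample_aucs <- function(recs)
    vapply(split(recs, recs$resample), function(d) auc_mw(d$prob, d$obs), 0)

  all_recs <- lapply(seq_len(nrow(grid)), function(gi)
    eval_candidate(grid[gi, , drop = FALSE]))
  grid_auc <- vapply(all_recs,
                     function(r) mean(resample_aucs(r), na.rm = TRUE), 0)
  best <- which.max(grid_auc)  # ties: first (lowest-complexity) row
  recs <- all_recs[[best]]
  aucs <- resample_aucs(recs)

  engine <- fit_learner(learner, x, y, grid[best, , drop = FALSE],
                        seed = sub_seed(seed, 99L))
  structure(list(
    learner = learner, best_params = grid[best, , drop = FALSE],
    grid = cbind(grid, cv_auc = grid_auc),
    cv_records = recs, cv_auc = mean(aucs, na.rm = TRUE),
    cv_auc_sd = stats::sd(aucs, na.rm = TRUE),
    engine = engine, x = x, y = y, seed = seed),
    class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s | n = %d, p = %d | CV AUC %.3f (+- %.3f)\n",
              toupper(x$learner), nrow(x$x), ncol(x$x),
              x$cv_auc, x$cv_auc_sd))
  cat("tuned:", paste(names(x$best_params),
                      signif(unlist(x$best_params), 4),
                      sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Predicted presence probabilities from a trained model
#'
#' @param object a [train_tuned()] model.
#' @param newdata data frame with the training feature columns.
#' @param ... unused.
#' @return numeric vector of positive-class probabilities.
#' @method predict trained_model
#' @export
predict.trained_model <- function(object, newdata, ...) {
  predict_prob(object$engine, as.data.frame(newdata))
}

#' Scaled variable importance
#'
#' Learner-native importance — gradient boosting: per-feature gain; random
#' forest: mean decrease in node impurity; SVM: a filter importance, the
#' class-separation AUC of each variable alone (folded around 0.5) — then
#' min-max scaled so the most important variable reads 100 and the least 0.
#'
#' @param model a [train_tuned()] model.
#' @return data frame with `variable` and `importance`, sorted decreasing.
#' @export
importance_scaled <- function(model) {
  feats <- model$engine$features
  raw <- switch(model$learner,
    gbm = {
      imp <- xgboost::xgb.importance(model = model$engine$fit)
      v <- stats::setNames(rep(0, length(feats)), feats)
      v[imp$Feature] <- imp$Gain
      v
    },
    rf = {
      im <- randomForest::importance(model$engine$fit)
      stats::setNames(im[, 1], rownames(im))[feats]
    },
    svm = {
      y <- model$y
      vapply(feats, function(f) {
        a <- auc_mw(model$x[[f]], y)
        abs(a - 0.5) * 2
      }, 0)
    })
  rng <- range(raw)
  sc <- if (diff(rng) == 0) rep(100, length(raw))
        else (raw - rng[1]) / diff(rng) * 100
  out <- data.frame(variable = names(raw), importance = unname(sc))
  out[order(-out$importance), ]
}

#' Partial dependence of the predicted presence probability
#'
#' For each grid value v of the chosen variable, the average predicted
#' positive-class probability over the training rows with that variable
#' forced to v (probability-fraction mode).
#'
#' @param model a [train_tuned()] model.
#' @param variable feature name.
#' @param grid_values evaluation points; default an equally spaced grid of
#'   `n_points` over the variable's observed range.
#' @param n_points grid size when `grid_values` is `NULL`.
#' @return data frame with columns `value` and `yhat`.
#' @export
partial_dependence <- function(model, variable, grid_values = NULL,
                               n_points = 20L) {
  if (!variable %in% names(model$x))
    stop("unknown variable: ", variable)
  if (is.null(grid_values))
    grid_values <- seq(min(model$x[[variable]]), max(model$x[[variable]]),
                       length.out = n_points)
  yhat <- vapply(grid_values, function(v) {
    xx <- model$x
    xx[[variable]] <- v
    mean(predict_prob(model$engine, xx))
  }, 0)
  data.frame(value = grid_values, yhat = yhat)
}

#' Evaluate a trained model on held-out data
#'
#' Classifies the test rows at probability 0.5 (the model-comparison
#' convention; the sensitivity-specificity balanced thresholds belong to the
#' mapping stage) and reports the five confusion-matrix metrics, the
#' test-set AUC, and the cross-validation AUC standard deviation carried
#' over from training.
#'
#' @param model a [train_tuned()] model.
#' @param x_test,y_test held-out features and labels.
#' @param threshold classification threshold (default 0.5).
#' @return list: `confusion`, `metrics`, `auc`, `auc_sd`, `prob`.
#' @export
evaluate_model <- function(model, x_test, y_test, threshold = 0.5) {
  prob <- predict_prob(model$engine, as.data.frame(x_test))
  pred <- ifelse(prob >= threshold, "present", "absent")
  cm <- confusion(pred, y_test)
  list(confusion = cm, metrics = classification_metrics(cm),
       auc = auc_mw(prob, y_test), auc_sd = model$cv_auc_sd, prob = prob)
}
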