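# Independent brute-force oracles and shared fixtures for the test suite.
# Oracles are written as plain double loops over window cells / score pairs,
# deliberately independent of the vectorized implementations they check.

grid_of <- function(m, cellsize = 1, xmin = 0, ymax = nrow(m) * cellsize) {
  raster_grid(m, xmin = xmin, ymax = ymax, cellsize = cellsize)
}

# focal statistic by explicit double loop with truncated windows
focal_oracle <- function(m, stat, window = 5L) {
  h <- (window - 1L) %/% 2L
  out <- matrix(NA_real_, nrow(m), ncol(m))
  for (r in seq_len(nrow(m))) {
    for (cc in seq_len(ncol(m))) {
      win <- m[max(1, r - h):min(nrow(m), r + h),
               max(1, cc - h):min(ncol(m), cc + h)]
      v <- win[!is.na(win)]
      out[r, cc] <- switch(stat,
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) >= 2) sd(v) else NA_real_,
        min = if (length(v)) min(v) else NA_real_)
    }
  }
  out
}

# Rao's Q of one window by the O(N^2) ordered-pair loop
rao_oracle_window <- function(v) {
  v <- v[!is.na(v)]
  n <- length(v)
  if (n < 2) return(NA_real_)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) q <- q + abs(v[i] - v[j])
  q / n^2
}

rao_oracle <- function(m, window = 5L) {
  h <- (window - 1L) %/% 2L
  out <- matrix(NA_real_, nrow(m), ncol(m))
  for (r in seq_len(nrow(m))) for (cc in seq_len(ncol(m)))
    out[r, cc] <- rao_oracle_window(
      m[max(1, r - h):min(nrow(m), r + h),
        max(1, cc - h):min(ncol(m), cc + h)])
  out
}

# AUC by trapezoidal integration of the empirical ROC curve
auc_trapezoid <- function(scores, labels) {
  y <- as.numeric(labels) > 0
  ts <- sort(unique(c(-Inf, scores, Inf)), decreasing = TRUE)
  se <- vapply(ts, function(t) mean(scores[y] >= t), 0)
  fp <- vapply(ts, function(t) mean(scores[!y] >= t), 0)
  sum(diff(fp) * (head(se, -1) + tail(se, -1)) / 2)
}

# reduced-rank regression oracle for the RDA eigenvalues
rda_eig_oracle <- function(Y, X) {
  Xs <- scale(as.matrix(X))
  Yc <- scale(as.matrix(Y), scale = FALSE)
  F <- qr.fitted(qr(cbind(1, Xs)), Yc)
  eigen(crossprod(F) / (nrow(Yc) - 1), symmetric = TRUE)$values
}

# threshold selection for one resample by exhaustive search (loop form)
threshold_oracle <- function(prob, pos) {
  best_t <- NA_real_; best_gap <- Inf
  for (t in seq_len(100) / 100) {
    se <- sum(prob[pos] >= t) / sum(pos)
    sp <- sum(prob[!pos] < t) / sum(!pos)
    if (abs(se - sp) < best_gap - 1e-12) {  # strict: keeps smallest on ties
      best_gap <- abs(se - sp); best_t <- t
    }
  }
  best_t
}

# one small scene shared across test files (built once per test run)
.test_scene_env <- new.env(parent = emptyenv())
get_test_scene <- function() {
  if (is.null(.test_scene_env$scene)) {
    cfg <- scene_config(extent = 300, seed = 7)
    .test_scene_env$scene <- generate_scene(cfg)
    .test_scene_env$layers <- rs_layers(.test_scene_env$scene$bands)
  }
  list(scene = .test_scene_env$scene, layers = .test_scene_env$layers)
}
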