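# compact suitability-map fixture: two one-feature models on a tiny site
tiny_map <- function(prob_e, prob_s, thresholds = c(E = 0.5, S = 0.5)) {
  nr <- nrow(prob_e)
  mask <- raster_grid(matrix(1, nr, ncol(prob_e)), 0, nr * 5, 5)
  g <- function(m) raster_grid(m, 0, nr * 5, 5)
  mk <- function(p, t) g(1 * (p >= t))
  structure(list(p_E = g(prob_e), p_S = g(prob_s),
                 mask_E = mk(prob_e, thresholds[["E"]]),
                 mask_S = mk(prob_s, thresholds[["S"]]),
                 mask_co = g(1 * (prob_e >= thresholds[["E"]] &
                                    prob_s >= thresholds[["S"]])),
                 thresholds = thresholds, pixel_area_m2 = 25),
            class = "suitability_map")
}

test_that("threshold selection balances sensitivity and specificity", {
  # fully separable scores: any threshold in (0.1, 0.9] ties at zero gap,
  # and the declared tie-break returns the smallest qualifying one
  rec <- data.frame(resample = 1,
                    obs = rep(c("present", "absent"), each = 10),
                    prob = rep(c(0.9, 0.1), each = 10))
  expect_equal(select_threshold(rec)$mean_threshold, 0.11)
  # scores identical to the 0/1 labels: 0.01 already gives Se = Sp = 1
  rec2 <- data.frame(resample = 1, obs = c(rep("present", 5), rep("absent", 5)),
                     prob = c(rep(1, 5), rep(0, 5)))
  expect_equal(select_threshold(rec2)$mean_threshold, 0.01)
  # exhaustive-search oracle agreement on random calibrated scores
  set.seed(41)
  for (i in 1:30) {
    n <- 60
    pos <- rep(c(TRUE, FALSE), each = n / 2)
    prob <- ifelse(pos, runif(n, 0.4, 1), runif(n, 0, 0.6))
    rec <- data.frame(resample = 1, obs = ifelse(pos, "present", "absent"),
                      prob = prob)
    expect_equal(select_threshold(rec)$mean_threshold,
                 threshold_oracle(prob, pos))
  }
  # single-class resamples are skipped with a warning, not fatal
  rec3 <- rbind(rec2, data.frame(resample = 2, obs = "present", prob = 0.7))
  expect_warning(out <- select_threshold(rec3), "skipped")
  expect_equal(out$n_skipped, 1L)
  expect_equal(out$mean_threshold, 0.01)
})

test_that("mean selected threshold sits near 0.5 for symmetric score overlap", {
  set.seed(42)
  means <- replicate(25, {
    n <- 400
    pos <- rep(c(TRUE, FALSE), each = n / 2)
    prob <- ifelse(pos, runif(n, 0.4, 1), runif(n, 0, 0.6))
    rec <- data.frame(resample = rep(1:4, length.out = n),
                      obs = ifelse(pos, "present", "absent"), prob = prob)
    select_threshold(rec)$mean_threshold
  })
  expect_lt(abs(mean(means) - 0.5), 0.05)
})

test_that("pixel maps binarize, intersect and propagate nodata", {
  set.seed(43)
  n <- 80
  x <- data.frame(temp = rnorm(n), wet = rnorm(n))
  y_e <- rbinom(n, 1, plogis(3 * x$temp))
  y_s <- rbinom(n, 1, plogis(3 * x$wet))
  m_e <- train_tuned(x, y_e, "rf", grid = data.frame(mtry = 2L), k = 4,
                     repeats = 1, seed = 44)
  m_s <- train_tuned(x, y_s, "rf", grid = data.frame(mtry = 2L), k = 4,
                     repeats = 1, seed = 45)
  site <- raster_grid(matrix(1, 4, 4), 0, 20, 5)
  feats <- data.frame(temp = rnorm(16), wet = rnorm(16))
  feats$temp[7] <- NA  # one incomplete landmark
  thr <- c(E = 0.457, S = 0.387)
  map <- predict_map(m_e, m_s, feats, site, thr)
  # intersection is the elementwise AND of the genus masks
  expect_equal(map$mask_co$data, map$mask_E$data * map$mask_S$data)
  expect_true(all(map$mask_co$data <= map$mask_E$data, na.rm = TRUE))
  expect_true(all(map$mask_co$data <= map$mask_S$data, na.rm = TRUE))
  # masks reproduce the thresholds applied to the probability surfaces
  expect_equal(map$mask_E$data, 1 * (map$p_E$data >= 0.457))
  expect_equal(map$mask_S$data, 1 * (map$p_S$data >= 0.387))
  # incomplete landmark is nodata everywhere (row-major cell 7 = row 2 col 3)
  expect_true(is.na(map$p_E$data[2, 3]) && is.na(map$mask_co$data[2, 3]))
  # raising a threshold never enlarges a mask
  map_hi <- predict_map(m_e, m_s, feats, site, c(E = 0.7, S = 0.387))
  expect_true(all(map_hi$mask_E$data <= map$mask_E$data, na.rm = TRUE))
  expect_error(predict_map(m_e, m_s, feats[1:3, ], site, thr), "landmark")
})

test_that("coverage accounting matches pixel counts and closes", {
  p_e <- matrix(c(1, 1, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0), 4) * 0.9
  p_s <- matrix(c(1, 0, 0, 0, 1, 1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0), 4) * 0.9
  map <- tiny_map(p_e, p_s)
  cov <- coverage(map)
  expect_equal(cov$pixels, c(4, 4, 2))
  expect_equal(cov$hectares, c(4, 4, 2) * 25 / 1e4)
  expect_equal(attr(cov, "site_area_ha"), 16 * 25 / 1e4)
  expect_equal(cov$percent, c(25, 25, 12.5))
  # explicit site area overrides the pixel-count area
  cov2 <- coverage(map, site_area_ha = 0.08)
  expect_equal(cov2$percent[1], 100 * 0.01 / 0.08)
  # the four exclusive categories tile the site exactly
  e_only <- sum(map$mask_E$data * (1 - map$mask_S$data))
  s_only <- sum(map$mask_S$data * (1 - map$mask_E$data))
  co <- sum(map$mask_co$data)
  neither <- sum((1 - map$mask_E$data) * (1 - map$mask_S$data))
  expect_equal(e_only + s_only + co + neither, 16)
  # empty map
  cov0 <- coverage(tiny_map(p_e * 0, p_s * 0))
  expect_equal(cov0$hectares, c(0, 0, 0))
  expect_equal(cov0$percent, c(0, 0, 0))
})

test_that("land-cover reclassification maps and conserves the source classes", {
  src <- raster_grid(matrix(c(2, 2, 3, 5, 6, 8, 7, 1, 4), 3), 0, 30, 10)
  broad <- reclassify_lulc(src)
  expect_equal(sum(broad$data == BROAD_CLASSES[["high_vegetation"]],
                   na.rm = TRUE), 2)
  expect_equal(sum(broad$data == BROAD_CLASSES[["low_vegetation"]],
                   na.rm = TRUE), 4)  # grass + crops + shrub + flooded veg
  expect_equal(sum(!is.na(broad$data)), 9)
  all_trees <- reclassify_lulc(raster_grid(matrix(2, 4, 4), 0, 40, 10))
  expect_true(all(all_trees$data == BROAD_CLASSES[["high_vegetation"]]))
  # snow/ice is excluded, unknown codes are loud errors
  snow <- reclassify_lulc(raster_grid(matrix(9, 2, 2), 0, 20, 10))
  expect_true(all(is.na(snow$data)))
  expect_error(reclassify_lulc(raster_grid(matrix(12, 2, 2), 0, 20, 10)),
               "12")
})

test_that("per-class presence percentages match hand counts", {
  # 4x4 site at 5 m; broad land cover at 10 m: quadrant classes
  broad <- raster_grid(matrix(c(1, 2, 2, 3), 2), 0, 20, 10)
  p_e <- matrix(0, 4, 4); p_e[1:2, 1:2] <- 1     # exactly the class-1 quadrant
  p_s <- matrix(0, 4, 4); p_s[1:2, 1:2] <- c(1, 0, 0, 1); p_s[3, 3] <- 1
  map <- tiny_map(p_e * 0.9, p_s * 0.9)
  cp <- class_presence(map, broad)
  hv <- cp[cp$class == "high_vegetation", ]
  expect_equal(hv$class_pixels, 4)
  expect_equal(hv$E, 100)            # mask identical to the class extent
  expect_equal(hv$S, 50)
  expect_equal(hv$co_invasion, 50)
  expect_true(all(is.na(cp[cp$class == "built_area", c("E", "S")])))
  # intersection bound holds class-wise
  ok <- !is.na(cp$co_invasion)
  expect_true(all(cp$co_invasion[ok] <= pmin(cp$E[ok], cp$S[ok]) + 1e-9))
})

test_that("Welch contrast and Cohen's d follow their definitions", {
  a <- c(0, 1, 2); b <- c(-1, 0, 1)      # sds exactly 1, means differ by 1
  gc <- group_contrast(a, b)
  expect_equal(gc$cohens_d, 1)
  expect_equal(gc$p_value, t.test(a, b)$p.value)
  same <- group_contrast(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$cohens_d, 0)
  expect_equal(same$p_value, 1)
  const <- group_contrast(c(2, 2), c(2, 2))   # zero pooled variance
  expect_true(is.na(const$cohens_d) && is.na(const$p_value))
  expect_error(group_contrast(1, 1:4), "at least 2")
  # Welch p agrees with a permutation test on unequal-variance samples
  set.seed(51)
  x <- rnorm(40, 0.8, 2); y <- rnorm(25, 0, 0.5)
  obs <- group_contrast(x, y)
  pooled <- c(x, y)
  perm_t <- replicate(4000, {
    idx <- sample(65, 40)
    t.test(pooled[idx], pooled[-idx])$statistic
  })
  p_perm <- mean(abs(perm_t) >= abs(obs$t))
  expect_lt(abs(obs$p_value - p_perm), 0.03)
})

test_that("histogram summaries reduce to the masked pixel multisets", {
  set.seed(52)
  vals <- matrix(runif(16, 10, 20), 4)
  layer <- raster_grid(vals, 0, 20, 5)
  p_e <- matrix(rbinom(16, 1, 0.5), 4)
  p_s <- matrix(rbinom(16, 1, 0.5), 4)
  map <- tiny_map(p_e * 0.9, p_s * 0.9)
  rep <- histogram_report(map, list(v = layer), breaks = 10)
  s <- rep$v$summary
  expect_equal(s$mean[s$category == "site"], mean(vals))
  expect_equal(s$mean[s$category == "E"], mean(vals[p_e == 1]))
  expect_equal(s$n[s$category == "co_invasion"], sum(p_e * p_s))
  # full coverage: category equals site
  full <- tiny_map(matrix(1, 4, 4), matrix(1, 4, 4))
  rf <- histogram_report(full, list(v = layer), breaks = 10)$v$summary
  expect_equal(rf$mean[rf$category == "E"], rf$mean[rf$category == "site"])
  # histogram counts sum to the group sizes
  h <- rep$v$histogram
  expect_equal(sum(h$count[h$category == "site"]), 16)
  # co-invasion mean lies between the E and S means on this shared layer
  ms <- s$mean[match(c("E", "S", "co_invasion"), s$category)]
  if (!any(is.na(ms)))
    expect_true(ms[3] >= min(ms[1:2]) - 1e-9 && ms[3] <= max(ms[1:2]) + 1e-9)
})
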