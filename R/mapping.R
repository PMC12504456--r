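#' Source land-cover class codes
#'
#' Integer codes of the 9-class source land-cover scheme used by the
#' synthetic generator and expected by [reclassify_lulc()] (the common
#' global 10-m land-cover taxonomy: water, trees, grass, flooded vegetation,
#' crops, shrub and scrub, built, bare, snow/ice).
#'
#' @format named integer vector.
#' @export
LULC_CODES <- c(water = 1L, trees = 2L, grass = 3L, flooded_vegetation = 4L,
                crops = 5L, shrub_and_scrub = 6L, built = 7L, bare = 8L,
                snow_and_ice = 9L)

#' Broad land-cover class codes
#'
#' Codes of the four broad classes used for invasion accounting, plus water.
#'
#' @format named integer vector.
#' @export
BROAD_CLASSES <- c(high_vegetation = 1L, low_vegetation = 2L,
                   bare_ground = 3L, built_area = 4L, water = 5L)

#' Sensitivity-specificity balanced probability threshold
#'
#' For each cross-validation resample, binarizes the held-out probabilities
#' at the 100 candidate thresholds 0.01, 0.02, ..., 1.00 and picks the
#' threshold minimizing |sensitivity - specificity| (smallest qualifying
#' threshold on ties, the sensitivity-conservative choice). The genus
#' threshold is the mean over resamples. A pixel/observation is classified
#' positive when its probability is >= the threshold. Resamples with a
#' single observed class are skipped with a warning.
#'
#' @param cv_records data frame with columns `resample`, `obs`
#'   (presence-absence), `prob` (held-out probability), as stored on a
#'   [train_tuned()] model.
#' @return list of class `threshold_result`: `mean_threshold`,
#'   `per_resample` (named vector), `n_resamples`, `n_skipped`.
#' @export
select_threshold <- function(cv_records) {
  thresholds <- seq_len(100L) / 100
  by_res <- split(cv_records, cv_records$resample)
  per <- rep(NA_real_, length(by_res))
  names(per) <- names(by_res)
  skipped <- 0L
  for (i in seq_along(by_res)) {
    d <- by_res[[i]]
    pos <- as_label(d$obs) == "present"
    if (all(pos) || !any(pos)) { skipped <- skipped + 1L; next }
    se <- vapply(thresholds, function(t) mean(d$prob[pos] >= t), 0)
    sp <- vapply(thresholds, function(t) mean(d$prob[!pos] < t), 0)
    per[i] <- thresholds[which.min(abs(se - sp))]  # which.min: first = smallest
  }
  if (skipped > 0L)
    warning(skipped, " single-class resample(s) skipped in threshold selection")
  ok <- !is.na(per)
  if (!any(ok)) stop("no resample had both classes")
  structure(list(mean_threshold = mean(per[ok]), per_resample = per[ok],
                 n_resamples = sum(ok), n_skipped = skipped),
            class = "threshold_result")
}

#' Pixel-based suitability and co-invasion map
#'
#' Predicts both genera's occurrence probabilities at every landmark pixel,
#' rasterizes them back onto the 5-m site grid, binarizes each at its genus
#' threshold (probability >= threshold), and intersects the two binary masks
#' into the co-invasion layer. Pixels with any missing feature are nodata in
#' all outputs.
#'
#' @param model_E,model_S [train_tuned()] models for the two genera.
#' @param landmark_features feature data frame for [landmarks()] of
#'   `site_mask`, in the same row-major order (as produced by
#'   [rs_features()]; the `x`/`y` columns are ignored).
#' @param site_mask 5-m [raster_grid()] whose positive cells are the site.
#' @param thresholds numeric `c(E = ..., S = ...)` genus thresholds.
#' @return list of class `suitability_map`: probability grids `p_E`, `p_S`,
#'   binary grids `mask_E`, `mask_S`, `mask_co`, the `thresholds` and the
#'   pixel area in m2.
#' @export
predict_map <- function(model_E, model_S, landmark_features, site_mask,
                        thresholds) {
  stopifnot(all(c("E", "S") %in% names(thresholds)))
  lm_pts <- landmarks(site_mask)
  feats <- landmark_features[, setdiff(names(landmark_features), c("x", "y")),
                             drop = FALSE]
  if (nrow(feats) != nrow(lm_pts))
    stop("landmark features do not match the site mask landmark count")
  ok <- stats::complete.cases(feats)
  prob_e <- prob_s <- rep(NA_real_, nrow(feats))
  if (any(ok)) {
    prob_e[ok] <- predict(model_E, feats[ok, , drop = FALSE])
    prob_s[ok] <- predict(model_S, feats[ok, , drop = FALSE])
  }
  rasterize <- function(v) {
    m <- matrix(NA_real_, nrow(site_mask$data), ncol(site_mask$data))
    rc <- point_cell(site_mask, lm_pts$x, lm_pts$y)
    m[cbind(rc$row, rc$col)] <- v
    raster_grid(m, site_mask$xmin, site_mask$ymax, site_mask$cellsize)
  }
  p_E <- rasterize(prob_e); p_S <- rasterize(prob_s)
  mk <- function(p, t) raster_grid(1 * (p$data >= t), p$xmin, p$ymax,
                                   p$cellsize)
  mask_E <- mk(p_E, thresholds[["E"]])
  mask_S <- mk(p_S, thresholds[["S"]])
  mask_co <- raster_grid(mask_E$data * mask_S$data, p_E$xmin, p_E$ymax,
                         p_E$cellsize)
  structure(list(p_E = p_E, p_S = p_S, mask_E = mask_E, mask_S = mask_S,
                 mask_co = mask_co, thresholds = thresholds,
                 pixel_area_m2 = site_mask$cellsize^2),
            class = "suitability_map")
}

#' Predicted cover in hectares and percent of site area
#'
#' Hectares = positive-pixel count x pixel area / 10^4; percent = 100 x
#' hectares / site area. With `site_area_ha = NULL` the site area is taken
#' as the total valid (non-nodata) pixel area of the map, so that the
#' E-only/S-only/co-invaded/neither accounting closes exactly.
#'
#' @param map a [predict_map()] result.
#' @param site_area_ha site area in hectares, or `NULL` for pixel-count
#'   area.
#' @return data frame with `category` (E, S, co_invasion), `hectares`,
#'   `percent`, plus the `site_area_ha` used as an attribute.
#' @export
coverage <- function(map, site_area_ha = NULL) {
  ha_per_px <- map$pixel_area_m2 / 1e4
  if (is.null(site_area_ha))
    site_area_ha <- sum(!is.na(map$mask_E$data)) * ha_per_px
  stopifnot(site_area_ha > 0)
  count <- c(E = sum(map$mask_E$data, na.rm = TRUE),
             S = sum(map$mask_S$data, na.rm = TRUE),
             co_invasion = sum(map$mask_co$data, na.rm = TRUE))
  ha <- count * ha_per_px
  out <- data.frame(category = names(count), pixels = unname(count),
                    hectares = unname(ha),
                    percent = unname(100 * ha / site_area_ha))
  attr(out, "site_area_ha") <- site_area_ha
  out
}

#' Reclassify source land cover into broad invasion-accounting classes
#'
#' trees become high vegetation; grass, crops, shrub/scrub and flooded
#' vegetation become low vegetation; bare stays bare ground; built stays
#' built area; water is retained as its own class; snow/ice is excluded
#' (nodata). Any code outside the source scheme is an error naming the
#' code.
#'
#' @param lulc [raster_grid()] of [LULC_CODES] values.
#' @return [raster_grid()] of [BROAD_CLASSES] codes (snow/ice as `NA`).
#' @export
reclassify_lulc <- function(lulc) {
  v <- lulc$data
  known <- v[!is.na(v)]
  bad <- setdiff(unique(known), unname(LULC_CODES))
  if (length(bad))
    stop("unknown land-cover class code(s): ", paste(bad, collapse = ", "))
  lut <- c(BROAD_CLASSES[["water"]],           # water
           BROAD_CLASSES[["high_vegetation"]], # trees
           BROAD_CLASSES[["low_vegetation"]],  # grass
           BROAD_CLASSES[["low_vegetation"]],  # flooded vegetation
           BROAD_CLASSES[["low_vegetation"]],  # crops
           BROAD_CLASSES[["low_vegetation"]],  # shrub and scrub
           BROAD_CLASSES[["built_area"]],      # built
           BROAD_CLASSES[["bare_ground"]],     # bare
           NA_real_)                           # snow/ice excluded
  out <- matrix(NA_real_, nrow(v), ncol(v))
  ok <- !is.na(v)
  out[ok] <- lut[v[ok]]
  raster_grid(out, lulc$xmin, lulc$ymax, lulc$cellsize)
}

#' Percent predicted presence per broad land-cover class
#'
#' Resamples the broad land-cover raster to the map's 5-m grid by nearest
#' (containing) cell and reports, for each broad class and each category
#' (genus E, genus S, co-invasion), `100 * |mask AND class| / |class|`.
#' Classes with no pixels on the site are reported as `NA`.
#'
#' @param map a [predict_map()] result.
#' @param broad_lulc [raster_grid()] of [BROAD_CLASSES] codes (any
#'   resolution on the shared frame).
#' @return data frame: `class`, `class_pixels`, `E`, `S`, `co_invasion`
#'   (percent).
#' @export
class_presence <- function(map, broad_lulc) {
  ctr <- landmarks(raster_grid(matrix(1, nrow(map$p_E$data),
                                      ncol(map$p_E$data)),
                               map$p_E$xmin, map$p_E$ymax,
                               map$p_E$cellsize))
  cls <- extract_at(ctr, list(cls = broad_lulc))$cls
  valid <- !is.na(map$mask_E$data)  # row-major order matches ctr
  cls_v <- cls[as.vector(t(valid))]
  masks <- list(E = map$mask_E, S = map$mask_S, co_invasion = map$mask_co)
  mask_v <- lapply(masks, function(m) as.vector(t(m$data))[as.vector(t(valid))])
  out <- do.call(rbind, lapply(names(BROAD_CLASSES), function(nm) {
    code <- BROAD_CLASSES[[nm]]
    in_cls <- !is.na(cls_v) & cls_v == code
    n <- sum(in_cls)
    pct <- vapply(mask_v, function(mv)
      if (n == 0L) NA_real_ else 100 * sum(mv[in_cls]) / n, 0)
    data.frame(class = nm, class_pixels = n, E = pct[["E"]], S = pct[["S"]],
               co_invasion = pct[["co_invasion"]])
  }))
  rownames(out) <- NULL
  out
}

#' Welch contrast and Cohen's d between two pixel-value groups
#'
#' Welch two-sample t-test (unequal variances, Satterthwaite degrees of
#' freedom, two-sided) and Cohen's d with the pooled standard deviation
#' `sqrt(((nA-1) sA^2 + (nB-1) sB^2) / (nA + nB - 2))`; positive d means
#' group A has the larger mean.
#'
#' @param values_a,values_b numeric samples (each n >= 2; `NA` dropped).
#' @return named list: `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`, `n_b`,
#'   `t`, `df`, `p_value`, `cohens_d` (`NA` p and d when the pooled variance
#'   is zero).
#' @export
group_contrast <- function(values_a, values_b) {
  a <- values_a[!is.na(values_a)]; b <- values_b[!is.na(values_b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  sa <- stats::sd(a); sb <- stats::sd(b)
  na <- length(a); nb <- length(b)
  s_pool <- sqrt(((na - 1) * sa^2 + (nb - 1) * sb^2) / (na + nb - 2))
  if (s_pool == 0) {
    d <- NA_real_; tt <- list(statistic = NA_real_, parameter = NA_real_,
                              p.value = NA_real_)
  } else {
    d <- (mean(a) - mean(b)) / s_pool
    tt <- stats::t.test(a, b, var.equal = FALSE)
  }
  list(mean_a = mean(a), sd_a = sa, n_a = na,
       mean_b = mean(b), sd_b = sb, n_b = nb,
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, cohens_d = d)
}

#' Per-variable distribution summaries for the map categories
#'
#' For each remote-sensing layer, extracts the pixel values at the map's
#' 5-m cell centers and summarizes their distribution for the whole site
#' and for the genus-E, genus-S and co-invasion masks: group means, SDs,
#' counts and shared-break histogram counts (the numeric content of the
#' usual per-site histogram panels).
#'
#' @param map a [predict_map()] result.
#' @param layers named list of [raster_grid()] layers.
#' @param breaks number of histogram bins (default 30).
#' @return named list (per variable) of lists with `summary` (data frame:
#'   category, mean, sd, n) and `histogram` (data frame: category, mid,
#'   count).
#' @export
histogram_report <- function(map, layers, breaks = 30L) {
  ctr <- landmarks(raster_grid(matrix(1, nrow(map$p_E$data),
                                      ncol(map$p_E$data)),
                               map$p_E$xmin, map$p_E$ymax, map$p_E$cellsize))
  vals <- extract_at(ctr, layers)
  valid <- as.vector(t(!is.na(map$mask_E$data)))
  cats <- list(
    site = valid,
    E = valid & as.vector(t(map$mask_E$data)) %in% 1,
    S = valid & as.vector(t(map$mask_S$data)) %in% 1,
    co_invasion = valid & as.vector(t(map$mask_co$data)) %in% 1
  )
  out <- list()
  for (nm in names(layers)) {
    v <- vals[[nm]]
    br <- seq(min(v[valid], na.rm = TRUE), max(v[valid], na.rm = TRUE),
              length.out = breaks + 1L)
    if (br[1] == br[length(br)]) br <- br[1] + c(-0.5, 0.5)
    summ <- do.call(rbind, lapply(names(cats), function(cn) {
      x <- v[cats[[cn]]]
      data.frame(category = cn, mean = mean(x, na.rm = TRUE),
                 sd = stats::sd(x, na.rm = TRUE), n = sum(!is.na(x)))
    }))
    hist_df <- do.call(rbind, lapply(names(cats), function(cn) {
      x <- v[cats[[cn]]]; x <- x[!is.na(x)]
      h <- graphics::hist(pmin(pmax(x, br[1]), br[length(br)]),
                          breaks = br, plot = FALSE)
      data.frame(category = cn, mid = h$mids, count = h$counts)
    }))
    out[[nm]] <- list(summary = summ, histogram = hist_df)
  }
  out
}
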