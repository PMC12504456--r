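#' Species counts for one plot
#'
#' Counts the species with positive cover, for the whole community and for
#' the native species only.
#'
#' @param plot_cover data frame with one row per species on the plot:
#'   columns `species_id`, `cover_pct`, `native_flag`.
#' @return named numeric vector `c(nbsp_all, nbsp_nat)`.
#' @export
species_counts <- function(plot_cover) {
  stopifnot(all(plot_cover$cover_pct >= 0))
  present <- plot_cover$cover_pct > 0
  c(nbsp_all = sum(present),
    nbsp_nat = sum(present & plot_cover$native_flag))
}

#' Community-weighted mean of a trait
#'
#' Cover-weighted average `sum(cover_i * trait_i) / sum(cover_i)` over the
#' plot's species with positive cover and a non-missing trait value
#' (missing-trait species are dropped from the affected combination).
#' Returns `NA` when no species qualifies, so the gap can propagate to
#' imputation rather than crash.
#'
#' @inheritParams species_counts
#' @param trait column name of the trait in `plot_cover`.
#' @param natives_only restrict to native species?
#' @return scalar CWM value, or `NA`.
#' @export
cwm <- function(plot_cover, trait, natives_only = FALSE) {
  d <- plot_cover[plot_cover$cover_pct > 0 & !is.na(plot_cover[[trait]]), ]
  if (natives_only) d <- d[d$native_flag, ]
  if (nrow(d) == 0L) return(NA_real_)
  sum(d$cover_pct * d[[trait]]) / sum(d$cover_pct)
}

## ----- convex hull volume (1-3 dimensions) ---------------------------------

## area of a 2-D convex hull via grDevices::chull + the shoelace formula
hull_area_2d <- function(p) {
  idx <- grDevices::chull(p[, 1], p[, 2])
  if (length(idx) < 3L) return(0)
  x <- p[idx, 1]; y <- p[idx, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

## exact-to-jitter 3-D hull volume: deterministic micro-jitter puts the
## points in general position, then every boundary facet is found exactly
## once by brute-force triple enumeration and the volume accumulated as
## tetrahedra against the centroid (interior point).
hull_volume_3d <- function(p) {
  dimnames(p) <- NULL
  n <- nrow(p)
  scale <- max(apply(p, 2, function(v) diff(range(v))), 1)
  p <- p + with_seed(987654L, matrix(stats::runif(3 * n, -1, 1), n, 3)) *
    (1e-9 * scale)
  ctr <- colMeans(p)
  vol <- 0
  tol <- 1e-12 * scale^3
  trips <- utils::combn(n, 3L)
  for (k in seq_len(ncol(trips))) {
    i <- trips[1L, k]; j <- trips[2L, k]; l <- trips[3L, k]
    u <- p[j, ] - p[i, ]; v <- p[l, ] - p[i, ]
    nrm <- c(u[2] * v[3] - u[3] * v[2],
             u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
    s <- (p[-c(i, j, l), , drop = FALSE] -
            matrix(p[i, ], n - 3L, 3L, byrow = TRUE)) %*% nrm
    if (all(s <= tol) || all(s >= -tol)) {
      a <- p[i, ] - ctr; b <- p[j, ] - ctr; cc <- p[l, ] - ctr
      vol <- vol + abs(a[1] * (b[2] * cc[3] - b[3] * cc[2]) -
                         a[2] * (b[1] * cc[3] - b[3] * cc[1]) +
                         a[3] * (b[1] * cc[2] - b[2] * cc[1])) / 6
    }
  }
  vol
}

#' Convex-hull volume of a point cloud in 1, 2 or 3 dimensions
#'
#' Range in 1-D, polygon area in 2-D, polyhedron volume in 3-D. Returns `NA`
#' when the points are rank-deficient in the given dimension (degenerate
#' hull), e.g. collinear points in 2-D or coplanar points in 3-D.
#'
#' @param p numeric matrix (points in rows, >= d + 1 points for dimension d).
#' @return nonnegative volume, or `NA` for a degenerate configuration.
#' @export
convex_hull_volume <- function(p) {
  p <- as.matrix(p)
  d <- ncol(p)
  if (d < 1L || d > 3L) stop("only 1-3 dimensional hulls are supported")
  if (nrow(p) < d + 1L) return(NA_real_)
  ctr <- scale(p, center = TRUE, scale = FALSE)
  sv <- svd(ctr)$d
  if (sum(sv > max(sv) * 1e-8) < d) return(NA_real_)  # rank-deficient
  unname(switch(d, diff(range(p[, 1])), hull_area_2d(p), hull_volume_3d(p)))
}

#' Standardize a trait table over the full species pool
#'
#' Centers and scales each trait over all species in the pool (not per plot),
#' so hull volumes are comparable across plots and invariant to the traits'
#' raw units.
#'
#' @param pool data frame with `species_id` and the trait columns.
#' @param traits character vector of trait column names.
#' @return numeric matrix of standardized traits, rownames = species ids.
#' @export
standardize_traits <- function(pool, traits = c("SLA", "SM", "H")) {
  m <- scale(as.matrix(pool[, traits, drop = FALSE]))
  rownames(m) <- pool$species_id
  m[, , drop = FALSE]
}

#' Functional Richness of one plot
#'
#' Convex-hull volume of the plot's species in trait space standardized over
#' the full species pool. When the number of species s is not greater than
#' the number of trait axes, the points are projected onto their s - 1
#' leading principal axes so that the hull has at least d + 1 points
#' (the axis reduction of the standard dbFD-style implementations). Returns
#' `NA` for fewer than two species or a degenerate (rank-deficient) hull.
#'
#' @inheritParams species_counts
#' @param trait_std standardized trait matrix from [standardize_traits()].
#' @param natives_only restrict to native species?
#' @return scalar FRic value, or `NA`.
#' @export
fric <- function(plot_cover, trait_std, natives_only = FALSE) {
  d <- plot_cover[plot_cover$cover_pct > 0, ]
  if (natives_only) d <- d[d$native_flag, ]
  ids <- intersect(unique(d$species_id), rownames(trait_std))
  pts <- trait_std[ids, , drop = FALSE]
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  s <- nrow(pts)
  if (s < 2L) return(NA_real_)
  dim_target <- min(ncol(pts), s - 1L)
  if (dim_target < ncol(pts)) {
    pc <- stats::prcomp(pts, center = TRUE, scale. = FALSE)
    pts <- pc$x[, seq_len(dim_target), drop = FALSE]
  }
  convex_hull_volume(pts)
}

#' Impute missing Functional Richness with a random-forest regression
#'
#' Fits a random forest of each FRic column on the remaining FD1 predictors
#' (species counts and the community-weighted means, plus the auxiliary leaf
#' dry matter content CWM, used for imputation only), on the rows where FRic
#' is observed, and fills the missing rows with its predictions. Reports the
#' out-of-bag R-squared per imputed column. Tree ensembles cannot
#' extrapolate, so imputed values stay within the observed range.
#'
#' @param features feature table containing `FRic.all` and/or `FRic.nat`
#'   with some missing values, plus the predictor columns.
#' @param predictors character vector of predictor column names.
#' @param seed integer seed for the forest.
#' @return list: `features` (gaps filled, plus logical columns
#'   `FRic.all.imputed` / `FRic.nat.imputed`), `r_squared` (named, OOB).
#' @export
impute_fric <- function(features,
                        predictors = c("nbsp.all", "nbsp.nat", "SLA.all",
                                       "SLA.nat", "SM.all", "SM.nat",
                                       "H.all", "H.nat", "LDMC.all"),
                        seed = 1L) {
  predictors <- intersect(predictors, names(features))
  r2 <- c()
  for (col in intersect(c("FRic.all", "FRic.nat"), names(features))) {
    flag_col <- paste0(col, ".imputed")
    miss <- is.na(features[[col]])
    features[[flag_col]] <- miss
    if (!any(miss)) next
    if (all(miss)) stop("no observed values to train the imputation on: ", col)
    x <- features[, predictors, drop = FALSE]
    x <- randomForest::na.roughfix(x)
    fit <- with_seed(seed, randomForest::randomForest(
      x = x[!miss, , drop = FALSE], y = features[[col]][!miss],
      ntree = 500))
    features[[col]][miss] <- stats::predict(fit, x[miss, , drop = FALSE])
    r2[col] <- utils::tail(fit$rsq, 1L)
  }
  list(features = features, r_squared = r2)
}

#' Succession axis: first NMDS axis of the presence-absence community table
#'
#' Runs nonmetric multidimensional scaling (2-D, stress-minimizing monotone
#' regression, best of `restarts` random starts) on Bray-Curtis (= Sorensen
#' for presence-absence) distances of the plots' species presence-absence
#' vectors and returns the axis-1 scores as the succession gradient. The
#' axis sign is fixed so the score correlates positively with `orient_by`
#' (community-weighted height by convention: succession builds taller
#' vegetation).
#'
#' @param comm plots x species presence-absence matrix (rownames = plot ids).
#' @param orient_by numeric vector (one value per plot) fixing the sign.
#' @param restarts number of random starts (default 20).
#' @param seed integer seed.
#' @return list: `scores` (named axis-1 scores), `stress`.
#' @export
succession_axis <- function(comm, orient_by = NULL, restarts = 20L,
                            seed = 1L) {
  comm <- as.matrix(comm) > 0
  storage.mode(comm) <- "numeric"
  if (nrow(comm) < 3L || ncol(comm) < 2L)
    stop("need at least 3 plots and 2 species")
  d <- vegan::vegdist(comm, method = "bray")
  if (max(d) == 0) stop("all plots are identical: zero-distance matrix")
  fit <- with_seed(seed, vegan::metaMDS(d, k = 2, try = restarts,
                                        trymax = restarts, trace = 0))
  sc <- vegan::scores(fit, display = "sites")[, 1]
  if (!is.null(orient_by)) {
    r <- suppressWarnings(stats::cor(sc, orient_by,
                                     use = "pairwise.complete.obs"))
    if (!is.na(r) && r < 0) sc <- -sc
  }
  names(sc) <- rownames(comm)
  list(scores = sc, stress = fit$stress)
}

#' Plot-level field-data feature table
#'
#' Computes the eleven field-data predictors for every plot of a sample:
#' species counts, Functional Richness, and community-weighted SLA, seed
#' mass and maximal height (each for all species and natives only), plus the
#' NMDS succession axis, followed by random-forest imputation of any FRic
#' gaps. Also carries the auxiliary `LDMC.all` CWM used only as an
#' imputation predictor.
#'
#' @param plot_sample a [sample_plots()] result (or equivalent list with
#'   `plots`, `cover`, `species_pool`).
#' @param nmds_restarts random restarts for the succession NMDS.
#' @param seed integer seed for imputation and NMDS.
#' @return list: `features` (one row per plot, FD columns + imputation
#'   flags), `imputation_r2`, `nmds_stress`.
#' @export
field_features <- function(plot_sample, nmds_restarts = 20L, seed = 1L) {
  plots <- plot_sample$plots
  cover <- plot_sample$cover
  trait_std <- standardize_traits(plot_sample$species_pool)
  by_plot <- split(cover, cover$plot_id)[plots$plot_id]

  one <- function(pc) {
    cnt <- species_counts(pc)
    c(cnt,
      FRic.all = fric(pc, trait_std, FALSE),
      FRic.nat = fric(pc, trait_std, TRUE),
      SLA.all = cwm(pc, "SLA", FALSE), SLA.nat = cwm(pc, "SLA", TRUE),
      SM.all = cwm(pc, "SM", FALSE), SM.nat = cwm(pc, "SM", TRUE),
      H.all = cwm(pc, "H", FALSE), H.nat = cwm(pc, "H", TRUE),
      LDMC.all = cwm(pc, "LDMC", FALSE))
  }
  feat <- as.data.frame(do.call(rbind, lapply(by_plot, one)))
  names(feat)[1:2] <- c("nbsp.all", "nbsp.nat")
  feat <- cbind(plot_id = plots$plot_id, feat, stringsAsFactors = FALSE)
  rownames(feat) <- NULL

  comm <- table(cover$plot_id, cover$species_id) > 0
  comm <- comm[plots$plot_id, , drop = FALSE]
  nmds <- succession_axis(comm, orient_by = feat$H.all,
                          restarts = nmds_restarts, seed = seed)
  feat$Succession <- unname(nmds$scores[plots$plot_id])

  imp <- impute_fric(feat, seed = seed)
  list(features = imp$features, imputation_r2 = imp$r_squared,
       nmds_stress = nmds$stress)
}

#' Names of the field-data predictor variables
#' @return character vector of the 11 FD variable names.
#' @export
fd_variable_names <- function() {
  c("nbsp.all", "nbsp.nat", "FRic.all", "FRic.nat", "SLA.all", "SLA.nat",
    "SM.all", "SM.nat", "H.all", "H.nat", "Succession")
}
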