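#' Configuration for a synthetic invasion landscape
#'
#' Defines the study conditions for the synthetic scene generator: a square
#' extent whose edge is divisible by 60 m (so the 1/5/10/20/30/60-m grids all
#' nest), the number of multi-temporal thermal/optical acquisition dates,
#' band noise levels, the two genera's niche coefficients on the latent
#' environmental fields, target prevalences, and one global seed from which
#' every stage derives its randomness by fixed sub-seeding.
#'
#' The default niches encode the two genera's contrasting ecology: genus E
#' (Erigeron-like, an early ruderal invader) favours hot, low, disturbed,
#' early-successional ground, while genus S (Solidago-like) favours moister
#' sites of intermediate height and succession (a quadratic penalty away from
#' mid-succession). Default prevalence is 0.40 per genus, which under these
#' overlapping niches yields roughly 20% joint prevalence.
#'
#' @param extent square scene edge length in metres; must be divisible by 60.
#' @param n_dates_landsat number of acquisition dates (>= 1) for the 30-m
#'   Red/NIR/thermal stacks.
#' @param kernel_sigma Gaussian smoothing bandwidth of the latent fields, in
#'   1-m cells; 0 leaves white noise.
#' @param noise named list of noise standard deviations: `chm` (m),
#'   `landsat`, `sentinel` (reflectance), `thermal` (degrees C), `tcdi`,
#'   `seli`.
#' @param cloud_prob probability that a date beyond the first carries cloud
#'   blobs (the first date is always clean so a per-pixel minimum recovers
#'   the clean optical signal, and a maximum the clean thermal signal).
#' @param niche per-genus lists with `linear` and `quad` coefficient vectors
#'   named after latent fields (`temperature`, `moisture`, `height`,
#'   `disturbance`, `succession`); applied to standardized fields.
#' @param prevalence target spatial mean occupancy probability per genus,
#'   each in (0, 1).
#' @param n_plots number of field plots (default 358).
#' @param plot_area_m2 plot area in square metres (default 28.3, a circular
#'   3-m radius plot).
#' @param n_species size of the synthetic species pool.
#' @param fd_signal strength of the occupancy signal routed exclusively
#'   through the field data (suppression of native richness on invaded
#'   plots); 0 disables it.
#' @param plot_placement `"random"` (uniform over the scene) or
#'   `"stratified"` (equal numbers across succession quartiles).
#' @param seed integer master seed.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(extent = 600,
                         n_dates_landsat = 10L,
                         kernel_sigma = 20,
                         noise = list(chm = 0.3, landsat = 0.01,
                                      sentinel = 0.005, thermal = 0.5,
                                      tcdi = 0.05, seli = 0.05),
                         cloud_prob = 0.3,
                         niche = list(
                           E = list(linear = c(temperature = 0.9,
                                               disturbance = 0.7,
                                               height = -0.9,
                                               succession = -0.6),
                                    quad = numeric(0)),
                           S = list(linear = c(moisture = 0.8,
                                               disturbance = 0.5),
                                    quad = c(succession = -0.5))),
                         prevalence = c(E = 0.40, S = 0.40),
                         n_plots = 358L,
                         plot_area_m2 = 28.3,
                         n_species = 60L,
                         fd_signal = 1,
                         plot_placement = c("random", "stratified"),
                         seed = 1L) {
  plot_placement <- match.arg(plot_placement)
  if (extent %% 60 != 0)
    stop("scene extent must be divisible by 60 m so all grids nest")
  if (n_dates_landsat < 1L) stop("need at least one acquisition date")
  if (any(prevalence <= 0) || any(prevalence >= 1))
    stop("target prevalences must lie in (0, 1)")
  structure(list(extent = extent,
                 n_dates_landsat = as.integer(n_dates_landsat),
                 kernel_sigma = kernel_sigma, noise = noise,
                 cloud_prob = cloud_prob, niche = niche,
                 prevalence = prevalence, n_plots = as.integer(n_plots),
                 plot_area_m2 = plot_area_m2,
                 n_species = as.integer(n_species), fd_signal = fd_signal,
                 plot_placement = plot_placement, seed = as.integer(seed)),
            class = "scene_config")
}

## run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## fixed per-stage sub-seeds derived from the master seed (kept < 2^31)
sub_seed <- function(seed, stage) {
  (as.double(seed) * 48271 + stage * 16807) %% 2147483647
}

## Gaussian smoothing of a matrix by separable row/column convolution with
## row-normalized truncated kernels (edge-safe, exactly linear in the input).
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  smoother <- function(n) {
    h <- ceiling(3 * sigma)
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1L, i - h):min(n, i + h)
      w <- exp(-((j - i)^2) / (2 * sigma^2))
      K[i, j] <- w / sum(w)
    }
    K
  }
  Kr <- smoother(nrow(m))
  Kc <- if (ncol(m) == nrow(m)) Kr else smoother(ncol(m))
  Kr %*% m %*% t(Kc)
}

std_field <- function(m) {
  s <- stats::sd(m)
  if (s == 0) return(m * 0)
  (m - mean(m)) / s
}

#' Generate spatially autocorrelated latent environmental fields
#'
#' Draws Gaussian white noise on the 1-m master grid and smooths it with a
#' fixed-width Gaussian kernel, producing the latent gradients every
#' downstream band and niche is built from: temperature (degrees C-like,
#' cooler under tall canopy), moisture, vegetation height (m, >= 0),
#' disturbance (higher where succession is young) and succession (a strictly
#' monotone transform of the height-generating field). A derived
#' `biomass` field in \[0, 1\] (monotone in moisture and succession) is
#' carried along for band synthesis. Deterministic under the config seed.
#'
#' @param config a [scene_config()].
#' @return A list of class `latent_fields` of [raster_grid()] layers:
#'   `temperature`, `moisture`, `height`, `disturbance`, `succession`,
#'   `biomass`, plus the standardized generator fields in `z`.
#' @export
make_latent_fields <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  n <- as.integer(config$extent)  # 1-m master grid
  z <- with_seed(sub_seed(config$seed, 1L), {
    raw <- replicate(4, matrix(stats::rnorm(n * n), n, n), simplify = FALSE)
    lapply(raw, function(m) std_field(gauss_smooth(m, config$kernel_sigma)))
  })
  names(z) <- c("h", "t", "m", "d")
  height <- 25 * stats::plogis(1.4 * z$h - 0.8)          # m, skewed low
  succession <- z$h                                      # monotone with height
  temperature <- 38 - 0.35 * height + 3 * z$t            # hot open ground
  moisture <- z$m - 0.3 * z$t
  disturbance <- 0.7 * z$d - 0.5 * z$h                   # young sites disturbed
  biomass <- stats::plogis(0.9 * std_field(moisture) + 0.6 * z$h)
  g <- function(m) raster_grid(m, xmin = 0, ymax = n, cellsize = 1)
  structure(list(temperature = g(temperature), moisture = g(moisture),
                 height = g(height), disturbance = g(disturbance),
                 succession = g(succession), biomass = g(biomass),
                 z = z, extent = n),
            class = "latent_fields")
}

## block-mean a 1-m latent matrix to the cell size cs (metres)
agg_to <- function(m, cs) block_stat(m, as.integer(cs), "mean")

clamp01 <- function(m) pmin(pmax(m, 0), 1)

## smooth random cloud blobs covering roughly `frac` of the scene
cloud_mask <- function(n_coarse, frac = 0.25) {
  m <- gauss_smooth(matrix(stats::rnorm(n_coarse^2), n_coarse, n_coarse), 3)
  m > stats::quantile(m, 1 - frac)
}

#' Synthesize the multi-resolution band stack from the latent fields
#'
#' Emits every raster the real-data pipeline would ingest, with the band-to-
#' environment relationships mirroring each band's environmental meaning:
#' a 1-m canopy height model; `n_dates_landsat` 30-m Red/NIR/thermal date
#' stacks (greener and cooler where biomass/moisture are high; dates after
#' the first may carry cloud blobs that brighten the optical bands and cool
#' the thermal band, so min/max compositing removes them); 10/20/60-m
#' reflectance bands clamped to \[0, 1\]; a 10-m disturbance index (TCDI,
#' increasing with the disturbance field); a 10-m leaf-area proxy (SeLI,
#' increasing with green biomass); and a 10-m land-cover class raster from
#' deterministic thresholds on the latents.
#'
#' @param latents a [make_latent_fields()] result.
#' @param config the matching [scene_config()].
#' @return A named list: `chm_1m`; lists `landsat_red`, `landsat_nir`,
#'   `landsat_thermal` (one [raster_grid()] per date); `s2` (named list of
#'   the seven Sentinel-2-like bands); `tcdi`, `seli`, `lulc`;
#'   `cloudy_dates` (logical per date, for diagnostics).
#' @export
make_bands <- function(latents, config) {
  stopifnot(inherits(latents, "latent_fields"))
  n <- latents$extent
  nz <- config$noise
  g <- function(m, cs) raster_grid(m, 0, n, cs)

  chm <- with_seed(sub_seed(config$seed, 2L), {
    pmax(latents$height$data + stats::rnorm(n * n, sd = nz$chm), 0)
  })

  bio30 <- agg_to(latents$biomass$data, 30)
  tmp30 <- agg_to(latents$temperature$data, 30)
  n30 <- n %/% 30L
  lst_scale <- 0.00341802; lst_offset <- 149.0
  landsat <- with_seed(sub_seed(config$seed, 3L), {
    cloudy <- c(FALSE, stats::runif(config$n_dates_landsat - 1L) < config$cloud_prob)
    dates <- lapply(seq_len(config$n_dates_landsat), function(d) {
      red <- clamp01(0.28 - 0.22 * bio30 +
                       matrix(stats::rnorm(n30^2, sd = nz$landsat), n30, n30))
      nir <- clamp01(0.15 + 0.45 * bio30 +
                       matrix(stats::rnorm(n30^2, sd = nz$landsat), n30, n30))
      lst_c <- tmp30 - abs(matrix(stats::rnorm(n30^2, sd = nz$thermal), n30, n30))
      if (cloudy[d]) {
        cm <- cloud_mask(n30)
        bump <- stats::runif(1, 0.2, 0.5)
        red[cm] <- clamp01(red[cm] + bump)
        nir[cm] <- clamp01(nir[cm] + bump)
        lst_c[cm] <- lst_c[cm] - stats::runif(1, 10, 20)  # clouds read cold
      }
      list(red = red, nir = nir,
           thermal = (lst_c + 273.15 - lst_offset) / lst_scale)
    })
    list(dates = dates, cloudy = cloudy)
  })

  s2 <- with_seed(sub_seed(config$seed, 4L), {
    zd <- std_field(latents$disturbance$data)
    zm <- std_field(latents$moisture$data)
    band <- function(expr_1m, cs) {
      m <- agg_to(expr_1m, cs)
      k <- n %/% as.integer(cs)
      clamp01(m + matrix(stats::rnorm(k^2, sd = nz$sentinel), k, k))
    }
    bio <- latents$biomass$data
    list(
      Aerosols = g(band(0.025 + 0.012 * zd, 60), 60),
      Blue     = g(band(0.05 - 0.02 * bio + 0.015 * zd, 10), 10),
      Green    = g(band(0.08 + 0.02 * bio, 10), 10),
      Red      = g(band(0.10 - 0.06 * bio + 0.02 * zd, 10), 10),
      RedEdge1 = g(band(0.08 + 0.10 * bio, 20), 20),
      NIR      = g(band(0.15 + 0.45 * bio, 10), 10),
      SWIR1    = g(band(0.30 - 0.10 * zm, 20), 20)
    )
  })

  extras <- with_seed(sub_seed(config$seed, 5L), {
    n10 <- n %/% 10L
    zd10 <- agg_to(std_field(latents$disturbance$data), 10)
    bio10 <- agg_to(latents$biomass$data, 10)
    tcdi <- 0.5 * zd10 + matrix(stats::rnorm(n10^2, sd = nz$tcdi), n10, n10)
    seli <- pmax(0.8 * bio10 +
                   matrix(stats::rnorm(n10^2, sd = nz$seli), n10, n10), 0)
    h10 <- agg_to(latents$height$data, 10)
    m10 <- agg_to(std_field(latents$moisture$data), 10)
    lulc <- matrix(LULC_CODES[["grass"]], n10, n10)
    lulc[bio10 < 0.30] <- LULC_CODES[["bare"]]
    lulc[bio10 >= 0.30 & zd10 > 0.6 & h10 <= 2] <- LULC_CODES[["crops"]]
    lulc[h10 > 2 & h10 <= 5] <- LULC_CODES[["shrub_and_scrub"]]
    lulc[h10 > 5] <- LULC_CODES[["trees"]]
    lulc[zd10 > 1.8 & h10 < 2] <- LULC_CODES[["built"]]
    lulc[m10 > 2.2 & h10 < 1] <- LULC_CODES[["water"]]
    list(tcdi = tcdi, seli = seli, lulc = lulc)
  })

  n10 <- n %/% 10L
  list(
    chm_1m = g(chm, 1),
    landsat_red = lapply(landsat$dates, function(d) g(d$red, 30)),
    landsat_nir = lapply(landsat$dates, function(d) g(d$nir, 30)),
    landsat_thermal = lapply(landsat$dates, function(d) g(d$thermal, 30)),
    s2 = s2,
    tcdi = g(extras$tcdi, 10),
    seli = g(extras$seli, 10),
    lulc = g(extras$lulc, 10),
    cloudy_dates = landsat$cloudy
  )
}

## logistic niche linear predictor (without intercept) on standardized fields
niche_eta <- function(latents, coefs) {
  n <- latents$extent
  eta <- matrix(0, n, n)
  zf <- function(nm) std_field(latents[[nm]]$data)
  for (nm in names(coefs$linear)) eta <- eta + coefs$linear[[nm]] * zf(nm)
  for (nm in names(coefs$quad)) eta <- eta + coefs$quad[[nm]] * zf(nm)^2
  eta
}

## bisection on the intercept so mean occupancy probability hits the target
calibrate_intercept <- function(eta, target, tol = 1e-4) {
  f <- function(a) mean(stats::plogis(a + eta)) - target
  lo <- -25; hi <- 25
  if (f(lo) > 0 || f(hi) < 0)
    stop("target prevalence unreachable under the niche coefficients")
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < tol * 1e-3) break
  }
  (lo + hi) / 2
}

#' Ground-truth occupancy probabilities and occupancy draws
#'
#' Builds each genus's occupancy probability surface from a logistic niche on
#' the standardized latent fields, auto-calibrating the intercept by
#' bisection so the spatial mean probability matches the target prevalence,
#' then draws per-pixel Bernoulli occupancies (independently per genus given
#' the landscape, so joint prevalence emerges from niche overlap).
#'
#' @inheritParams make_bands
#' @return A list of class `truth_layer`: probability grids `p_E`, `p_S`,
#'   occupancy grids `occupancy_E`, `occupancy_S` (0/1), and the calibrated
#'   `intercepts`.
#' @export
make_truth <- function(latents, config) {
  stopifnot(inherits(latents, "latent_fields"))
  if (!all(vapply(config$niche, function(g)
    all(is.finite(c(g$linear, g$quad))), TRUE)))
    stop("niche coefficients must be finite")
  n <- latents$extent
  g <- function(m) raster_grid(m, 0, n, 1)
  eta_e <- niche_eta(latents, config$niche$E)
  eta_s <- niche_eta(latents, config$niche$S)
  a_e <- calibrate_intercept(eta_e, config$prevalence[["E"]])
  a_s <- calibrate_intercept(eta_s, config$prevalence[["S"]])
  p_e <- stats::plogis(a_e + eta_e)
  p_s <- stats::plogis(a_s + eta_s)
  occ <- with_seed(sub_seed(config$seed, 6L), {
    list(e = matrix(stats::rbinom(n * n, 1, p_e), n, n),
         s = matrix(stats::rbinom(n * n, 1, p_s), n, n))
  })
  structure(list(p_E = g(p_e), p_S = g(p_s),
                 occupancy_E = g(occ$e), occupancy_S = g(occ$s),
                 intercepts = c(E = a_e, S = a_s)),
            class = "truth_layer")
}

## deterministic synthetic species pool with traits and nativity
make_species_pool <- function(config) {
  with_seed(sub_seed(config$seed, 7L), {
    ns <- config$n_species
    aff <- stats::runif(ns)                     # succession affinity in [0,1]
    pool <- data.frame(
      species_id = sprintf("sp%03d", seq_len(ns)),
      succ_affinity = aff,
      SLA = exp(stats::rnorm(ns, 3.0, 0.35)),   # cm2/g
      SM = exp(stats::rnorm(ns, 0, 1.2)),       # g
      H = exp(0.3 + 2.0 * aff + stats::rnorm(ns, 0, 0.3)),  # m, taller late
      LDMC = exp(stats::rnorm(ns, 5.5, 0.25)),  # mg/g, imputation aid only
      native_flag = TRUE,
      stringsAsFactors = FALSE
    )
    ## invaders: two Erigeron-like, two Solidago-like, plus two other aliens
    alien <- c(1:2, 3:4, 5:6)
    pool$native_flag[alien] <- FALSE
    pool$species_id[1:2] <- c("erigeron_a", "erigeron_b")
    pool$species_id[3:4] <- c("solidago_a", "solidago_b")
    pool$succ_affinity[1:2] <- c(0.05, 0.15)    # early ruderals
    pool$succ_affinity[3:4] <- c(0.45, 0.55)    # mid succession
    pool$H[1:2] <- c(0.9, 1.1); pool$H[3:4] <- c(1.4, 1.6)
    pool
  })
}

#' Sample field plots with species composition, traits and genus labels
#'
#' Places `n_plots` plot centers on distinct 1-m cells (uniformly at random,
#' or stratified over succession quartiles), reads each genus's label from
#' the occupancy draw at the plot location, and generates a plot x species
#' cover table from the synthetic pool: native richness rises with the
#' succession field, species are drawn by succession affinity (so
#' composition turns over along the gradient and community-weighted height
#' rises with the height field), and invader species are added where the
#' occupancy says so. When `fd_signal > 0`, native richness is additionally
#' suppressed on invaded plots, routing part of the genus signal exclusively
#' through the field-data features.
#'
#' @param truth a [make_truth()] result.
#' @inheritParams make_bands
#' @return A list of class `plot_sample`: `plots` (plot_id, x, y, per-genus
#'   labels, latent values at the plot), `cover` (long plot x species cover
#'   table with nativity and traits), `species_pool`.
#' @export
sample_plots <- function(truth, latents, config) {
  n <- latents$extent
  if (config$n_plots > n * n) stop("more plots requested than grid cells")
  pool <- make_species_pool(config)
  with_seed(sub_seed(config$seed, 8L), {
    succ <- latents$succession$data
    if (config$plot_placement == "stratified") {
      qs <- cut(succ, stats::quantile(succ, 0:4 / 4), include.lowest = TRUE)
      per <- diff(round(seq(0, config$n_plots, length.out = 5)))
      cells <- unlist(lapply(1:4, function(k)
        sample(which(as.integer(qs) == k), per[k])))
    } else {
      cells <- sample.int(n * n, config$n_plots)
    }
    row <- (cells - 1L) %% n + 1L
    col <- (cells - 1L) %/% n + 1L
    succ_pct <- stats::ecdf(succ)(succ[cells])
    occ_e <- truth$occupancy_E$data[cells]
    occ_s <- truth$occupancy_S$data[cells]

    plots <- data.frame(
      plot_id = sprintf("plot%03d", seq_along(cells)),
      x = 0 + (col - 0.5) * 1, y = n - (row - 0.5) * 1,
      area_m2 = config$plot_area_m2,
      genusE_present = occ_e, genusS_present = occ_s,
      succession = succ[cells],
      height = latents$height$data[cells],
      temperature = latents$temperature$data[cells],
      stringsAsFactors = FALSE
    )

    nat <- pool[pool$native_flag, ]
    cover_rows <- vector("list", nrow(plots))
    for (i in seq_len(nrow(plots))) {
      lam <- exp(log(9) + 0.5 * std1(succ_pct[i]) -
                   config$fd_signal * (0.30 * occ_e[i] + 0.25 * occ_s[i]))
      k <- max(2L, min(nrow(nat), stats::rpois(1, lam)))
      w <- exp(-(nat$succ_affinity - succ_pct[i])^2 / (2 * 0.22^2)) + 1e-6
      pick <- sample(nrow(nat), k, prob = w)
      ids <- nat$species_id[pick]
      ## invaders present per the occupancy labels
      if (occ_e[i]) ids <- c(ids, sample(c("erigeron_a", "erigeron_b"), 1))
      if (occ_s[i]) ids <- c(ids, sample(c("solidago_a", "solidago_b"), 1))
      cover_rows[[i]] <- data.frame(
        plot_id = plots$plot_id[i], species_id = ids,
        cover_pct = round(exp(stats::rnorm(length(ids), 1.6, 0.8)), 2),
        stringsAsFactors = FALSE)
    }
    cover <- do.call(rbind, cover_rows)
    cover <- merge(cover, pool[, c("species_id", "native_flag",
                                   "SLA", "SM", "H", "LDMC")],
                   by = "species_id", sort = FALSE)
    cover <- cover[order(cover$plot_id, cover$species_id), ]
    rownames(cover) <- NULL
    structure(list(plots = plots, cover = cover, species_pool = pool),
              class = "plot_sample")
  })
}

## center a probability-like scalar around 0 on a +-1-ish scale
std1 <- function(p) 2 * (p - 0.5)

#' Generate a complete synthetic scene
#'
#' Convenience wrapper running [make_latent_fields()], [make_bands()],
#' [make_truth()] and [sample_plots()] under one configuration.
#'
#' @inheritParams make_latent_fields
#' @return list with `config`, `latents`, `bands`, `truth`, `plots`.
#' @export
generate_scene <- function(config = scene_config()) {
  latents <- make_latent_fields(config)
  bands <- make_bands(latents, config)
  truth <- make_truth(latents, config)
  plots <- sample_plots(truth, latents, config)
  list(config = config, latents = latents, bands = bands,
       truth = truth, plots = plots)
}

#' Write a scene to disk as plain-text rasters and CSV tables
#'
#' Rasters go out as ESRI ASCII grids (see [write_ascii_grid()]), the plot
#' and cover tables as CSV.
#'
#' @param scene a [generate_scene()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  b <- scene$bands
  write_ascii_grid(b$chm_1m, file.path(dir, "chm_1m.asc"))
  for (d in seq_along(b$landsat_red)) {
    write_ascii_grid(b$landsat_red[[d]], file.path(dir, sprintf("landsat_red_%02d.asc", d)))
    write_ascii_grid(b$landsat_nir[[d]], file.path(dir, sprintf("landsat_nir_%02d.asc", d)))
    write_ascii_grid(b$landsat_thermal[[d]], file.path(dir, sprintf("landsat_thermal_%02d.asc", d)))
  }
  for (nm in names(b$s2))
    write_ascii_grid(b$s2[[nm]], file.path(dir, sprintf("s2_%s.asc", tolower(nm))))
  write_ascii_grid(b$tcdi, file.path(dir, "tcdi.asc"))
  write_ascii_grid(b$seli, file.path(dir, "seli.asc"))
  write_ascii_grid(b$lulc, file.path(dir, "lulc.asc"))
  utils::write.csv(scene$plots$plots, file.path(dir, "plots.csv"), row.names = FALSE)
  utils::write.csv(scene$plots$cover, file.path(dir, "plot_species_cover.csv"),
                   row.names = FALSE)
  invisible(dir)
}
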