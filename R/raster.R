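#' Single-band planar raster grid
#'
#' Lightweight container for one co-registered single-band raster on a planar
#' metric CRS. Values are stored as a numeric matrix with row 1 / column 1 at
#' the grid's top-left corner; `NA` encodes nodata. Layers are aligned by
#' coordinates (origin + cell size), never by array index, so grids of
#' different resolutions can be used together as long as they share the
#' coordinate frame.
#'
#' @param data numeric matrix; row 1 is the northernmost row.
#' @param xmin x coordinate of the grid's left (west) edge, in metres.
#' @param ymax y coordinate of the grid's top (north) edge, in metres.
#' @param cellsize cell edge length in metres (> 0).
#' @return An object of class `raster_grid` with fields `data`, `xmin`,
#'   `ymax`, `cellsize`.
#' @examples
#' g <- raster_grid(matrix(1:12, 3, 4), xmin = 0, ymax = 30, cellsize = 10)
#' dim(g$data)
#' @export
raster_grid <- function(data, xmin, ymax, cellsize) {
  if (!is.matrix(data)) data <- as.matrix(data)
  storage.mode(data) <- "double"
  stopifnot(is.numeric(xmin), is.numeric(ymax), cellsize > 0)
  structure(
    list(data = data, xmin = as.numeric(xmin), ymax = as.numeric(ymax),
         cellsize = as.numeric(cellsize)),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf(
    "<raster_grid> %d rows x %d cols @ %g m | x [%g, %g] y [%g, %g] | %d nodata\n",
    nrow(x$data), ncol(x$data), x$cellsize,
    x$xmin, x$xmin + ncol(x$data) * x$cellsize,
    x$ymax - nrow(x$data) * x$cellsize, x$ymax,
    sum(is.na(x$data))))
  invisible(x)
}

#' @rdname raster_grid
#' @param x object to test.
#' @export
is_raster_grid <- function(x) inherits(x, "raster_grid")

#' Cell-center coordinates of a raster grid
#'
#' @param grid a [raster_grid()].
#' @return list with `x` (column centers, west to east) and `y` (row centers,
#'   north to south).
#' @export
cell_centers <- function(grid) {
  cs <- grid$cellsize
  list(
    x = grid$xmin + (seq_len(ncol(grid$data)) - 0.5) * cs,
    y = grid$ymax - (seq_len(nrow(grid$data)) - 0.5) * cs
  )
}

same_grid <- function(a, b, tol = 1e-9) {
  is_raster_grid(a) && is_raster_grid(b) &&
    all(dim(a$data) == dim(b$data)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymax - b$ymax) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

check_same_grid <- function(a, b) {
  if (!same_grid(a, b)) stop("rasters are not co-registered on the same grid")
  invisible(TRUE)
}

## shift a matrix by (dr, dc); vacated cells become NA
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  r1 <- max(1, 1 - dr); r2 <- min(nr, nr - dr)
  c1 <- max(1, 1 - dc); c2 <- min(nc, nc - dc)
  if (r1 <= r2 && c1 <= c2) {
    r_dst <- r1:r2; c_dst <- c1:c2
    out[r_dst, c_dst] <- m[r_dst + dr, c_dst + dc]
  }
  out
}

#' Per-pixel composite over a multi-date stack
#'
#' Reduces a stack of co-registered single-band rasters (one per acquisition
#' date) to a single band by the per-pixel minimum or maximum over the
#' non-missing dates, the standard cheap cloud/gap filter for multi-temporal
#' imagery: cloud-brightened optical pixels are removed by the minimum,
#' cloud-cooled thermal pixels by the maximum. A pixel is missing only if it
#' is missing on every date.
#'
#' @param stack list of [raster_grid()] objects on one grid (>= 1 date).
#' @param reducer `"min"` or `"max"`.
#' @return A [raster_grid()].
#' @export
composite <- function(stack, reducer = c("min", "max")) {
  reducer <- match.arg(reducer)
  if (!is.list(stack) || length(stack) < 1L)
    stop("composite() needs a non-empty list of rasters")
  ref <- stack[[1L]]
  for (g in stack) check_same_grid(ref, g)
  f <- if (reducer == "min") pmin else pmax
  acc <- ref$data
  for (g in stack[-1L]) acc <- f(acc, g$data, na.rm = TRUE)
  raster_grid(acc, ref$xmin, ref$ymax, ref$cellsize)
}

#' Normalized Difference Vegetation Index
#'
#' NDVI = (NIR - Red) / (NIR + Red), computed element-wise on co-registered
#' reflectance grids. Pixels where NIR + Red = 0 are set missing.
#'
#' @param red,nir co-registered [raster_grid()] reflectance bands.
#' @return A [raster_grid()] with values in \[-1, 1\] for nonnegative inputs.
#' @export
ndvi <- function(red, nir) {
  check_same_grid(red, nir)
  den <- nir$data + red$data
  out <- (nir$data - red$data) / den
  out[!is.na(den) & den == 0] <- NA_real_
  raster_grid(out, red$xmin, red$ymax, red$cellsize)
}

#' Land surface temperature from thermal digital numbers
#'
#' Applies the data producer's linear radiometric rescaling to Kelvin and
#' converts to degrees Celsius: `celsius = scale * DN + offset - 273.15`.
#' Defaults are the Landsat Collection-2 surface-temperature constants
#' (scale 0.00341802, offset 149.0).
#'
#' @param thermal [raster_grid()] of thermal-band digital numbers.
#' @param scale,offset producer rescaling constants (scale > 0).
#' @return A [raster_grid()] in degrees Celsius.
#' @export
lst <- function(thermal, scale = 0.00341802, offset = 149.0) {
  stopifnot(scale > 0)
  raster_grid(scale * thermal$data + offset - 273.15,
              thermal$xmin, thermal$ymax, thermal$cellsize)
}

#' NIRv: NDVI times NIR reflectance
#'
#' Element-wise product NDVI x NIR, a proxy for radiation actually absorbed
#' by green canopy, more robust than NDVI at low leaf area.
#'
#' @param ndvi_layer [raster_grid()] of NDVI values.
#' @param nir co-registered [raster_grid()] NIR reflectance.
#' @return A [raster_grid()].
#' @export
nirv <- function(ndvi_layer, nir) {
  check_same_grid(ndvi_layer, nir)
  raster_grid(ndvi_layer$data * nir$data,
              nir$xmin, nir$ymax, nir$cellsize)
}

#' Moving-window focal statistic
#'
#' Per-pixel mean, standard deviation (n - 1 denominator) or minimum over an
#' odd-sized square window of non-missing cells. Edge pixels use the
#' truncated window (no padding); a pixel is missing only if every window
#' cell is missing (for `sd`, also if fewer than two cells are valid).
#'
#' @param grid a [raster_grid()].
#' @param stat one of `"mean"`, `"sd"`, `"min"`.
#' @param window odd window edge length in cells (default 5).
#' @return A [raster_grid()] on the same grid.
#' @export
focal_stat <- function(grid, stat = c("mean", "sd", "min"), window = 5L) {
  stat <- match.arg(stat)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("focal window must be an odd positive integer")
  m <- grid$data
  h <- (window - 1L) %/% 2L
  offs <- expand.grid(dr = -h:h, dc = -h:h)
  if (stat == "min") {
    acc <- matrix(NA_real_, nrow(m), ncol(m))
    for (i in seq_len(nrow(offs)))
      acc <- pmin(acc, shift_mat(m, offs$dr[i], offs$dc[i]), na.rm = TRUE)
    return(raster_grid(acc, grid$xmin, grid$ymax, grid$cellsize))
  }
  s1 <- matrix(0, nrow(m), ncol(m))
  s2 <- matrix(0, nrow(m), ncol(m))
  n  <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(offs))) {
    v <- shift_mat(m, offs$dr[i], offs$dc[i])
    ok <- !is.na(v)
    v[!ok] <- 0
    s1 <- s1 + v
    s2 <- s2 + v * v
    n  <- n + ok
  }
  if (stat == "mean") {
    out <- ifelse(n > 0, s1 / n, NA_real_)
  } else {
    out <- ifelse(n > 1, pmax(s2 - s1^2 / n, 0) / (n - 1), NA_real_)
    out <- sqrt(out)
  }
  raster_grid(out, grid$xmin, grid$ymax, grid$cellsize)
}

## block statistics over f x f cell blocks (used for grid aggregation)
block_stat <- function(m, f, stat = c("mean", "sd")) {
  stat <- match.arg(stat)
  if (nrow(m) %% f != 0L || ncol(m) %% f != 0L)
    stop("grid dimensions are not a multiple of the aggregation factor")
  rg <- rep(seq_len(nrow(m) %/% f), each = f)
  cg <- rep(seq_len(ncol(m) %/% f), each = f)
  two_way <- function(x) t(rowsum(t(rowsum(x, rg)), cg))
  mm <- m; mm[is.na(m)] <- 0
  s1 <- two_way(mm)
  n  <- two_way(matrix(as.numeric(!is.na(m)), nrow(m), ncol(m)))
  if (stat == "mean") return(ifelse(n > 0, s1 / n, NA_real_))
  s2 <- two_way(mm * mm)
  sqrt(ifelse(n > 1, pmax(s2 - s1^2 / n, 0) / (n - 1), NA_real_))
}

#' Aggregate a 1-m canopy height model to 5-m height statistics
#'
#' Each 5-m cell receives the mean and the sample standard deviation of the
#' 25 underlying 1-m cells, i.e. the 5 x 5 focal statistics evaluated exactly
#' at the 5-m cell centers (block statistics). The 1-m grid must nest in the
#' 5-m grid.
#'
#' @param chm_1m [raster_grid()] canopy height model at 1-m resolution.
#' @param factor integer aggregation factor (default 5).
#' @return list with [raster_grid()] elements `CHMmean` and `CHMsd`.
#' @export
chm_to_5m <- function(chm_1m, factor = 5L) {
  f <- as.integer(factor)
  if (nrow(chm_1m$data) %% f != 0L || ncol(chm_1m$data) %% f != 0L)
    stop("1-m grid does not nest in the aggregated grid")
  cs <- chm_1m$cellsize * f
  list(
    CHMmean = raster_grid(block_stat(chm_1m$data, f, "mean"),
                          chm_1m$xmin, chm_1m$ymax, cs),
    CHMsd   = raster_grid(block_stat(chm_1m$data, f, "sd"),
                          chm_1m$xmin, chm_1m$ymax, cs)
  )
}

## Rao's Q of a sorted numeric vector with pairwise |vi - vj| distances:
## sum over ordered pairs / n^2, using the sorted-sum identity.
rao_q_values <- function(v) {
  v <- v[!is.na(v)]
  n <- length(v)
  if (n < 2L) return(NA_real_)
  v <- sort(v)
  pair_sum <- sum(v * (2 * seq_len(n) - n - 1))  # sum_{i<j} (v_j - v_i)
  2 * pair_sum / n^2
}

#' Moving-window Rao's quadratic entropy
#'
#' Spectral-diversity surrogate for functional diversity: for each pixel,
#' `Q = sum_i sum_j d_ij p_i p_j` over all ordered pairs of the N valid cells
#' in the window, with equal weights `p_i = 1/N` and absolute-difference
#' distances `d_ij = |v_i - v_j|` (the i = j zero terms are included in the
#' N^2 normalization). Pixels with fewer than two valid window cells are
#' missing; edges use the truncated window.
#'
#' @inheritParams focal_stat
#' @return A [raster_grid()] of nonnegative Q values.
#' @export
rao_q <- function(grid, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("focal window must be an odd positive integer")
  m <- grid$data
  nr <- nrow(m); nc <- ncol(m)
  h <- (window - 1L) %/% 2L
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    rr <- max(1L, r - h):min(nr, r + h)
    for (cc in seq_len(nc)) {
      cw <- max(1L, cc - h):min(nc, cc + h)
      out[r, cc] <- rao_q_values(m[rr, cw])
    }
  }
  raster_grid(out, grid$xmin, grid$ymax, grid$cellsize)
}

## map point coordinates to (row, col); NA when outside the extent.
## Cells are half-open intervals [x0, x0 + cs) in x and (y0 - cs, y0] ... the
## same convention top-down: a point on a shared edge belongs to the cell
## right/below of it, except the outer max edge which is out of extent.
point_cell <- function(grid, x, y) {
  cs <- grid$cellsize
  col <- floor((x - grid$xmin) / cs) + 1
  row <- floor((grid$ymax - y) / cs) + 1
  bad <- col < 1 | col > ncol(grid$data) | row < 1 | row > nrow(grid$data)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Extract multi-resolution layer values at point locations
#'
#' For each point and each layer, returns the stored value of the cell
#' containing the point (no interpolation), so nearby points can share a
#' coarse-cell value while differing at finer resolutions. Points outside a
#' layer's extent get a missing value for that layer, with a warning.
#'
#' @param points data frame with numeric columns `x` and `y` (metres).
#' @param layers named list of [raster_grid()] objects.
#' @return data frame: `x`, `y`, then one numeric column per layer.
#' @export
extract_at <- function(points, layers) {
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    stop("layers must be a named list")
  out <- data.frame(x = points$x, y = points$y)
  n_outside <- 0L
  for (nm in names(layers)) {
    g <- layers[[nm]]
    rc <- point_cell(g, points$x, points$y)
    vals <- rep(NA_real_, nrow(points))
    ok <- !is.na(rc$row)
    n_outside <- max(n_outside, sum(!ok))
    vals[ok] <- g$data[cbind(rc$row[ok], rc$col[ok])]
    out[[nm]] <- vals
  }
  if (n_outside > 0L)
    warning(sprintf("%d point(s) fall outside a layer's extent; values set missing",
                    n_outside))
  out
}

#' Landmark coordinates: centers of the true cells of a mask
#'
#' Returns the center coordinates of every positive cell of a (typically 5-m)
#' site mask, in row-major order (top row first, west to east), the pixel
#' population over which site-level suitability is predicted.
#'
#' @param site_mask [raster_grid()] whose nonzero, non-missing cells define
#'   the site.
#' @return data frame with columns `x`, `y` (one row per landmark).
#' @export
landmarks <- function(site_mask) {
  m <- site_mask$data
  keep <- which(t(!is.na(m) & m != 0))  # t() => row-major order
  if (length(keep) == 0L) stop("site mask has no positive cells")
  nc <- ncol(m)
  row <- (keep - 1L) %/% nc + 1L
  col <- (keep - 1L) %% nc + 1L
  cs <- site_mask$cellsize
  data.frame(x = site_mask$xmin + (col - 0.5) * cs,
             y = site_mask$ymax - (row - 0.5) * cs)
}

#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text single-band raster exchange format readable by standard GIS
#' software; nodata cells are written as -9999.
#'
#' @param grid a [raster_grid()].
#' @param path file path.
#' @param nodata nodata sentinel written to file.
#' @return `write_ascii_grid()` returns `path` invisibly; `read_ascii_grid()`
#'   returns a [raster_grid()].
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  m <- grid$data
  m[is.na(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", grid$xmin),
    sprintf("yllcorner %.10g", grid$ymax - nrow(m) * grid$cellsize),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %.10g", nodata)
  )
  body <- apply(m, 1L, function(r) paste(format(r, trim = TRUE, digits = 10),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1L))
  vals <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(vals) <- keys
  nr <- as.integer(vals[["nrows"]]); nc <- as.integer(vals[["ncols"]])
  m <- matrix(scan(text = paste(lines[-(1:6)], collapse = "\n"),
                   quiet = TRUE), nrow = nr, ncol = nc, byrow = TRUE)
  m[m == vals[["nodata_value"]]] <- NA_real_
  raster_grid(m, vals[["xllcorner"]],
              vals[["yllcorner"]] + nr * vals[["cellsize"]],
              vals[["cellsize"]])
}
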