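#' Derive the full set of remote-sensing predictor layers
#'
#' Turns the raw band stack of a scene into the 16 predictor layers used by
#' the classifiers, at their native resolutions:
#' \itemize{
#'   \item `CHMmean`, `CHMsd` (5 m): block mean / sd of the 1-m canopy
#'     height model ([chm_to_5m()]);
#'   \item `NDVI` (30 m): per-pixel minimum composite of the Red and NIR
#'     date stacks first, then [ndvi()] (compositing the bands before the
#'     index, which differs from compositing per-date NDVI);
#'   \item `LST` (30 m, degrees C): per-pixel maximum composite of the
#'     thermal digital numbers (yearly extreme heat), then [lst()];
#'   \item the seven reflectance bands `Aerosols` (60 m), `Blue`, `Green`,
#'     `Red`, `NIR` (10 m), `RedEdge1`, `SWIR1` (20 m), passed through;
#'   \item `TCDImean`, `TCDIsd` (10 m): 5 x 5 focal mean / sd of the
#'     disturbance index;
#'   \item `SeLImin` (10 m): 5 x 5 focal minimum of the leaf-area proxy;
#'   \item `RaoQ_NDVI` (30 m) and `RaoQ_NIRv` (10 m): 5 x 5 moving-window
#'     Rao's quadratic entropy of NDVI and of NIRv (the latter from the 10-m
#'     Sentinel-like Red/NIR bands via [nirv()]).
#' }
#'
#' @param bands a band list as produced by [make_bands()] (or assembled from
#'   files with the same structure).
#' @param lst_scale,lst_offset producer constants for the thermal rescaling,
#'   see [lst()].
#' @param window focal window edge length in cells (default 5).
#' @return Named list of 16 [raster_grid()] layers.
#' @export
rs_layers <- function(bands, lst_scale = 0.00341802, lst_offset = 149.0,
                      window = 5L) {
  chm <- chm_to_5m(bands$chm_1m)
  red30 <- composite(bands$landsat_red, "min")
  nir30 <- composite(bands$landsat_nir, "min")
  ndvi30 <- ndvi(red30, nir30)
  lst30 <- lst(composite(bands$landsat_thermal, "max"),
               scale = lst_scale, offset = lst_offset)
  ndvi10 <- ndvi(bands$s2$Red, bands$s2$NIR)
  nirv10 <- nirv(ndvi10, bands$s2$NIR)
  list(
    CHMmean = chm$CHMmean,
    CHMsd = chm$CHMsd,
    NDVI = ndvi30,
    LST = lst30,
    Aerosols = bands$s2$Aerosols,
    Blue = bands$s2$Blue,
    Green = bands$s2$Green,
    Red = bands$s2$Red,
    RedEdge1 = bands$s2$RedEdge1,
    NIR = bands$s2$NIR,
    SWIR1 = bands$s2$SWIR1,
    TCDImean = focal_stat(bands$tcdi, "mean", window),
    TCDIsd = focal_stat(bands$tcdi, "sd", window),
    SeLImin = focal_stat(bands$seli, "min", window),
    RaoQ_NDVI = rao_q(ndvi30, window),
    RaoQ_NIRv = rao_q(nirv10, window)
  )
}

#' Names of the remote-sensing predictor variables
#' @return character vector of the 16 layer names.
#' @export
rs_variable_names <- function() {
  c("CHMmean", "CHMsd", "NDVI", "LST", "Aerosols", "Blue", "Green", "Red",
    "RedEdge1", "NIR", "SWIR1", "TCDImean", "TCDIsd", "SeLImin",
    "RaoQ_NDVI", "RaoQ_NIRv")
}

#' Extract remote-sensing features at plot centers or landmark pixels
#'
#' Thin wrapper over [extract_at()]: one row per point, one column per
#' derived layer, values taken from the cell containing the point at each
#' layer's own resolution.
#'
#' @param layers result of [rs_layers()].
#' @param points data frame with `x`, `y` columns (plot centers or
#'   [landmarks()] output).
#' @return data frame of features (plus the `x`, `y` columns).
#' @export
rs_features <- function(layers, points) {
  extract_at(points, layers)
}
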