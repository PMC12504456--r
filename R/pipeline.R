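#' End-to-end co-invasion modelling pipeline on a synthetic scene
#'
#' Runs the full workflow the package exists for, on one generated
#' landscape:
#' \enumerate{
#'   \item generate the scene ([generate_scene()]) and derive the 16
#'     remote-sensing predictor layers ([rs_layers()]);
#'   \item extract remote-sensing features at the plot centers and compute
#'     the field-data features ([field_features()]);
#'   \item per genus: stratified 75/25 partition, AUC-tuned training of the
#'     requested learner on the fused FD+RS features and on the RS-only
#'     features, test-set evaluation at probability 0.5;
#'   \item redundancy analysis of the test-set predicted probabilities on
#'     the fused explanatory matrix, with VIFs ([rda_probs()]);
#'   \item final models on all plots with RS features only, sensitivity-
#'     specificity balanced thresholds from their cross-validation records
#'     ([select_threshold()]), pixel-based probability/binary/co-invasion
#'     maps over the whole scene ([predict_map()]), coverage accounting,
#'     broad land-cover class presence and group contrasts of the key
#'     predictors between the two genera's suitable pixels.
#' }
#'
#' The computational geometry (scene extent, tuning grid, NMDS restarts)
#' defaults to a desk-scale configuration; all of it can be widened through
#' the arguments.
#'
#' @param config a [scene_config()].
#' @param learner learner for all stages (default `"gbm"`).
#' @param grid tuning grid (default: a compact gradient-boosting grid,
#'   n.trees 100/200 x interaction.depth 2/3).
#' @param k,repeats cross-validation geometry (default 10 x 10).
#' @param stages character subset of `c("fused", "rs_only", "final")`;
#'   `"final"` implies the mapping steps.
#' @param contrast_vars layer names contrasted between the genus masks.
#' @param nmds_restarts random restarts for the succession NMDS.
#' @return A list with elements `scene`, `layers`, `features` (fused table
#'   with labels), `models` (per genus x stage), `evaluation`, `rda`,
#'   `final` (models, thresholds, map, coverage, class_presence,
#'   contrasts).
#' @export
run_pipeline <- function(config = scene_config(),
                         learner = "gbm",
                         grid = expand.grid(n.trees = c(100L, 200L),
                                            interaction.depth = c(2L, 3L)),
                         k = 10L, repeats = 10L,
                         stages = c("fused", "rs_only", "final"),
                         contrast_vars = c("LST", "CHMmean", "SeLImin",
                                           "RedEdge1"),
                         nmds_restarts = 10L) {
  stages <- match.arg(stages, several.ok = TRUE)
  seed <- config$seed
  scene <- generate_scene(config)
  layers <- rs_layers(scene$bands)
  pts <- scene$plots$plots[, c("x", "y")]
  rs <- rs_features(layers, pts)
  rs$x <- NULL; rs$y <- NULL
  labels <- data.frame(E = scene$plots$plots$genusE_present,
                       S = scene$plots$plots$genusS_present)
  fd <- NULL; fused <- rs
  if ("fused" %in% stages) {  # field features feed the fused stage only
    fd <- field_features(scene$plots, nmds_restarts = nmds_restarts,
                         seed = seed)
    fused <- cbind(fd$features[, fd_variable_names()], rs)
  }

  models <- list(); evaluation <- list()
  parts <- list()
  for (g in c("E", "S")) {
    parts[[g]] <- partition(labels[[g]], 0.75,
                            seed = sub_seed(seed, 21L + (g == "S")))
    for (st in intersect(stages, c("fused", "rs_only"))) {
      x <- if (st == "fused") fused else rs
      tr <- parts[[g]]$train; te <- parts[[g]]$test
      m <- train_tuned(x[tr, , drop = FALSE], labels[[g]][tr],
                       learner = learner, grid = grid, k = k,
                       repeats = repeats,
                       seed = sub_seed(seed, 31L + 2 * (g == "S") +
                                         (st == "rs_only")))
      models[[g]][[st]] <- m
      evaluation[[g]][[st]] <-
        evaluate_model(m, x[te, , drop = FALSE], labels[[g]][te])
    }
  }

  rda_res <- NULL
  if ("fused" %in% stages) {
    te <- parts$E$test  # one shared explanatory/test frame for ordination
    Y <- cbind(E = predict(models$E$fused, fused[te, , drop = FALSE]),
               S = predict(models$S$fused, fused[te, , drop = FALSE]))
    rda_res <- rda_probs(Y, fused[te, , drop = FALSE])
  }

  final <- NULL
  if ("final" %in% stages) {
    fm <- lapply(c(E = "E", S = "S"), function(g)
      train_tuned(rs, labels[[g]], learner = learner, grid = grid, k = k,
                  repeats = repeats,
                  seed = sub_seed(seed, 41L + (g == "S"))))
    thr <- vapply(fm, function(m)
      select_threshold(m$cv_records)$mean_threshold, 0)
    n5 <- config$extent %/% 5L
    site_mask <- raster_grid(matrix(1, n5, n5), 0, config$extent, 5)
    lmk <- landmarks(site_mask)
    lmk_feats <- rs_features(layers, lmk)
    map <- predict_map(fm$E, fm$S, lmk_feats, site_mask, thr)
    broad <- reclassify_lulc(scene$bands$lulc)
    contrasts <- lapply(stats::setNames(contrast_vars, contrast_vars),
                        function(v) {
      vals <- extract_at(lmk, layers[v])[[v]]
      group_contrast(vals[as.vector(t(map$mask_E$data)) %in% 1],
                     vals[as.vector(t(map$mask_S$data)) %in% 1])
    })
    final <- list(models = fm, thresholds = thr, map = map,
                  coverage = coverage(map),
                  class_presence = class_presence(map, broad),
                  contrasts = contrasts)
  }

  list(scene = scene, layers = layers,
       features = cbind(fused, labels), field = fd,
       partitions = parts, models = models, evaluation = evaluation,
       rda = rda_res, final = final)
}
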