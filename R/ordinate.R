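#' Redundancy analysis of predicted occurrence probabilities
#'
#' Constrains the two genera's predicted occurrence probabilities (the
#' response matrix Y, centered) on the fused field + remote-sensing
#' explanatory matrix X by multivariate least squares followed by an
#' eigen-decomposition of the fitted values (the engine is [vegan::rda()]).
#' Explanatory columns are standardized to unit variance by default, since
#' field and remote-sensing variables live on wildly different scales.
#' Scores are returned in type-2 scaling (correlation biplot: the effects of
#' the explanatory variables), together with per-variable variance inflation
#' factors for redundancy screening.
#'
#' @param Y numeric matrix/data frame of responses (n x 2 here: probability
#'   of occurrence per genus); constant columns are an error.
#' @param X numeric data frame of explanatory variables.
#' @param standardize scale X columns to unit variance (default TRUE).
#' @param vif_threshold redundancy flag threshold (default 10).
#' @return list of class `rda_result`: `eigenvalues` (constrained),
#'   `proportion_constrained`, `biplot_scores` (explanatory arrows),
#'   `response_scores`, `site_scores`, `vif`, `vif_flagged`,
#'   `rank_deficient`, and the underlying vegan `model`.
#' @export
rda_probs <- function(Y, X, standardize = TRUE, vif_threshold = 10) {
  Y <- as.matrix(Y)
  X <- as.data.frame(X)
  if (nrow(Y) < 3L) stop("need at least 3 observations")
  if (any(apply(Y, 2, stats::sd) == 0))
    stop("constant response column: RDA undefined")
  Xm <- as.matrix(X)
  if (standardize) Xm <- scale(Xm)
  rank_def <- qr(cbind(1, Xm))$rank < ncol(Xm) + 1L
  mod <- vegan::rda(Y ~ ., data = as.data.frame(Xm))
  eig <- unname(mod$CCA$eig)
  total <- mod$tot.chi
  sc_bp <- vegan::scores(mod, display = "bp", scaling = 2,
                         choices = seq_along(eig))
  sc_sp <- vegan::scores(mod, display = "sp", scaling = 2,
                         choices = seq_along(eig))
  sc_si <- vegan::scores(mod, display = "sites", scaling = 2,
                         choices = seq_along(eig))
  v <- vif_values(X)
  structure(list(
    eigenvalues = eig,
    proportion_constrained = sum(eig) / total,
    total_variance = total,
    residual_eigenvalues = unname(mod$CA$eig),
    biplot_scores = sc_bp, response_scores = sc_sp, site_scores = sc_si,
    vif = v, vif_flagged = names(v)[is.infinite(v) | v > vif_threshold],
    rank_deficient = rank_def, model = mod),
    class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf("<rda_result> %d constrained axes | %.1f%% of variance constrained\n",
              length(x$eigenvalues), 100 * x$proportion_constrained))
  if (length(x$vif_flagged))
    cat("VIF-flagged (redundant):", paste(x$vif_flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from the least-squares
#' regression of explanatory variable j on all the others. A perfectly
#' collinear variable is reported as `Inf`, not an error. Values above 10
#' conventionally flag redundant variables.
#'
#' @param X numeric data frame or matrix with at least two columns.
#' @return named numeric vector of VIFs (all >= 1 for full-rank X).
#' @export
vif_values <- function(X) {
  X <- as.data.frame(X)
  if (ncol(X) < 2L) stop("VIF needs at least two variables")
  vapply(seq_len(ncol(X)), function(j) {
    ## exact collinearity gives a perfect fit; reported as Inf, so the
    ## near-singular lm warnings are expected noise here
    fit <- stats::lm(X[[j]] ~ ., data = X[, -j, drop = FALSE])
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0) |> stats::setNames(names(X))
}
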