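#' Fit a z-score scaler on training vectors
#'
#' Per-dimension mean and (sample) standard deviation over the training
#' windows only; constant dimensions get unit scale so transformed values
#' are zero rather than undefined. Test data must be transformed with the
#' training statistics ([apply_scaler()]), never refit.
#'
#' @param X Training matrix, windows x dimensions.
#' @return A `feature_scaler` with `center`, `scale` and the indices of
#'   constant dimensions.
#' @export
fit_scaler <- function(X) {
  if (nrow(X) < 2) stop("need at least 2 training vectors to fit a scaler")
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  const <- which(!is.finite(scale) | scale == 0)
  scale[const] <- 1
  structure(list(center = center, scale = scale, constant = const),
            class = "feature_scaler")
}

#' Apply a fitted scaler
#' @param scaler A [fit_scaler()] result.
#' @param X Matrix (or single vector) to transform.
#' @return Transformed matrix.
#' @export
apply_scaler <- function(scaler, X) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  sweep(sweep(X, 2, scaler$center), 2, scaler$scale, "/")
}

#' Fit a variance-constrained PCA projection
#'
#' Principal components of the scaled training matrix (singular value
#' decomposition of the centred data). The retained dimensionality D is the
#' smallest number of components whose cumulative explained variance
#' reaches `var_target`, subject to the dual constraint D <= number of
#' dimensions and D <= number of training samples - 1; when the variance
#' target is unreachable under that cap, D is the cap and a warning is
#' issued. Component signs follow a deterministic convention (the largest-
#' magnitude loading of each component is positive).
#'
#' @param X Scaled training matrix, windows x dimensions.
#' @param var_target Cumulative explained-variance target (default 0.95).
#' @return A `pca_projection` with `rotation` (dimensions x D), `center`,
#'   `D` and `explained_variance_ratio` (all computed components).
#' @export
fit_pca <- function(X, var_target = 0.95) {
  n <- nrow(X)
  if (n < 2) stop("need at least 2 training vectors for PCA")
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  total <- sum(ev)
  if (total <= 1e-24) stop("degenerate training set: no variance")
  evr <- ev / total
  cum <- cumsum(evr)
  cap <- min(ncol(X), n - 1)
  d_target <- which(cum >= var_target - 1e-12)[1]
  if (is.na(d_target)) d_target <- length(ev)
  D <- min(d_target, cap)
  if (cum[D] < var_target - 1e-12) {
    warning(sprintf(
      "variance target %.2f unreachable under sample cap: D = %d explains %.3f",
      var_target, D, cum[D]))
  }
  rot <- p$rotation[, seq_len(D), drop = FALSE]
  for (j in seq_len(D)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  }
  structure(list(rotation = rot, center = p$center, D = D,
                 explained_variance_ratio = evr),
            class = "pca_projection")
}

#' Project vectors with a fitted PCA
#' @param projection A [fit_pca()] result.
#' @param X Matrix (windows x dimensions) or single vector.
#' @return windows x D score matrix.
#' @export
apply_pca <- function(projection, X) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != nrow(projection$rotation)) {
    stop("input dimensionality does not match the fitted projection")
  }
  sweep(X, 2, projection$center) %*% projection$rotation
}
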