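#' Replace Tukey-fence outliers with quartile values
#'
#' Values below \eqn{Q_1 - k \cdot IQR} are replaced by the 25th percentile
#' and values above \eqn{Q_3 + k \cdot IQR} by the 75th percentile; everything
#' else passes through. Quartiles use linear interpolation
#' (`stats::quantile` type 7). With a constant column the fences collapse onto
#' the constant and nothing changes.
#'
#' @param column Numeric vector, length >= 4.
#' @param k Fence multiplier (default 1.5, the Tukey convention).
#' @param name Column name used in error messages.
#' @return Vector of the same length with outliers winsorised.
#' @examples
#' winsorize_outliers(c(1, 2, 3, 4, 100))  # 100 -> 4
#' @export
winsorize_outliers <- function(column, k = 1.5, name = deparse(substitute(column))) {
  if (!is.numeric(column)) {
    stop(sprintf("column '%s' must be numeric", name), call. = FALSE)
  }
  stopifnot(length(column) >= 4L)
  fit <- winsorize_fit(column, k = k)
  winsorize_apply(column, fit)
}

# Fences and replacement quantiles learned from (training) data.
winsorize_fit <- function(x, k = 1.5) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  list(q1 = q[1], q3 = q[2], lower = q[1] - k * iqr, upper = q[2] + k * iqr)
}

winsorize_apply <- function(x, fit) {
  x[x < fit$lower] <- fit$q1
  x[x > fit$upper] <- fit$q3
  x
}

#' Principal-component reduction retaining a variance fraction
#'
#' Centres the feature matrix, computes principal components and keeps the
#' smallest number of leading components whose cumulative explained-variance
#' ratio reaches `variance_retained`. The returned transform can be applied to
#' held-out data with [pca_apply()], which is what keeps cross-validation
#' leakage-free.
#'
#' @param features Numeric matrix or data.frame, samples x features.
#' @param variance_retained Fraction of variance to keep, in `(0, 1]`.
#' @return List with `scores` (reduced matrix), `rotation`, `center`,
#'   `n_components`, `explained` (per-component variance ratios).
#' @export
pca_reduce <- function(features, variance_retained = 0.95) {
  stopifnot(variance_retained > 0, variance_retained <= 1)
  x <- as.matrix(features)
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ratio <- p$sdev^2 / sum(p$sdev^2)
  ncomp <- which(cumsum(ratio) >= variance_retained - 1e-12)[1]
  if (is.na(ncomp)) ncomp <- length(ratio)
  list(scores = p$x[, seq_len(ncomp), drop = FALSE],
       rotation = p$rotation[, seq_len(ncomp), drop = FALSE],
       center = p$center,
       n_components = ncomp,
       explained = ratio)
}

#' @rdname pca_reduce
#' @param fit A transform from [pca_reduce()].
#' @param newdata Samples x features matrix with the original columns.
#' @export
pca_apply <- function(fit, newdata) {
  x <- sweep(as.matrix(newdata), 2, fit$center)
  x %*% fit$rotation
}

# Full preprocessing transform fitted on training rows only:
# per-column winsorisation -> standardisation -> PCA.
preprocess_fit <- function(x, variance_retained = 0.95, fence_k = 1.5) {
  x <- as.matrix(x)
  wins <- lapply(seq_len(ncol(x)), function(j) winsorize_fit(x[, j], k = fence_k))
  xw <- x
  for (j in seq_len(ncol(x))) xw[, j] <- winsorize_apply(x[, j], wins[[j]])
  mu <- colMeans(xw)
  sdv <- apply(xw, 2, stats::sd)
  sdv[sdv == 0] <- 1
  xs <- sweep(sweep(xw, 2, mu), 2, sdv, `/`)
  pca <- pca_reduce(xs, variance_retained)
  list(wins = wins, mu = mu, sd = sdv, pca = pca)
}

preprocess_apply <- function(fit, x) {
  x <- as.matrix(x)
  for (j in seq_len(ncol(x))) x[, j] <- winsorize_apply(x[, j], fit$wins[[j]])
  x <- sweep(sweep(x, 2, fit$mu), 2, fit$sd, `/`)
  pca_apply(fit$pca, x)
}
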