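#' Configuration for the synthetic two-class tabular generator
#'
#' Defaults emulate the Wisconsin diagnostic breast-cancer table: 357
#' benign-like and 212 malignant-like samples, 30 numeric features of which
#' 10 are informative, a correlated feature block mimicking the
#' radius/perimeter/area redundancy, a sprinkling of multiplicative outliers,
#' and pure-noise columns.
#'
#' @param n_class0,n_class1 Sample counts per class (label 0 / label 1).
#' @param n_features Total feature count.
#' @param n_informative Number of informative features (<= `n_features`); the
#'   rest are standard-normal noise.
#' @param class_separation Mahalanobis distance between the two class means
#'   with respect to the informative-block covariance; 0 means no signal.
#' @param correlated_block_size Size of the leading informative block given
#'   compound-symmetry correlation `block_correlation`.
#' @param block_correlation Pairwise correlation inside the block.
#' @param outlier_fraction Fraction of cells multiplied by `outlier_scale`.
#' @param outlier_scale Multiplier (> 1) applied to outlier cells.
#' @param seed Integer seed; generation is a pure function of the config.
#' @return List of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_class0 = 357, n_class1 = 212, n_features = 30,
                             n_informative = 10, class_separation = 4,
                             correlated_block_size = min(5, n_informative),
                             block_correlation = 0.7,
                             outlier_fraction = 0.02, outlier_scale = 10,
                             seed = 7) {
  cfg <- list(n_class0 = n_class0, n_class1 = n_class1,
              n_features = n_features, n_informative = n_informative,
              class_separation = class_separation,
              correlated_block_size = correlated_block_size,
              block_correlation = block_correlation,
              outlier_fraction = outlier_fraction,
              outlier_scale = outlier_scale, seed = seed)
  with(cfg, {
    if (n_class0 <= 0 || n_class1 <= 0) stop("class counts must be > 0", call. = FALSE)
    if (n_informative > n_features) stop("n_informative must be <= n_features", call. = FALSE)
    if (correlated_block_size > n_informative) {
      stop("correlated_block_size must be <= n_informative", call. = FALSE)
    }
    if (class_separation < 0) stop("class_separation must be >= 0", call. = FALSE)
    if (outlier_fraction < 0 || outlier_fraction >= 1) {
      stop("outlier_fraction must be in [0, 1)", call. = FALSE)
    }
    if (outlier_fraction > 0 && outlier_scale <= 1) {
      stop("outlier_scale must be > 1", call. = FALSE)
    }
    if (block_correlation < 0 || block_correlation >= 1) {
      stop("block_correlation must be in [0, 1)", call. = FALSE)
    }
  })
  structure(cfg, class = "synthetic_config")
}

#' Generate a labeled two-class Gaussian-mixture table
#'
#' Informative features are drawn from two multivariate Gaussians whose means
#' differ by `class_separation` (Mahalanobis distance) along a random
#' direction; the leading `correlated_block_size` informative features share
#' compound-symmetry correlation. The remaining features are standard-normal
#' noise in both classes. A random `outlier_fraction` of cells is multiplied
#' by `outlier_scale` to mimic heavy-tailed measurement errors. Fully
#' reproducible from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return data.frame with columns `feature_01..feature_NN` and `label` (0
#'   rows first, then 1), with the config stored in `attr(, "config")`.
#' @examples
#' d <- generate_synthetic(synthetic_config(n_class0 = 40, n_class1 = 30,
#'                                          n_features = 5, n_informative = 3,
#'                                          correlated_block_size = 2))
#' table(d$label)
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n0 <- config$n_class0
  n1 <- config$n_class1
  p <- config$n_features
  p_inf <- config$n_informative
  n <- n0 + n1
  withr_seed(config$seed, {
    # informative covariance: compound-symmetry block, identity elsewhere
    sigma <- diag(p_inf)
    b <- config$correlated_block_size
    if (b >= 2) {
      sigma[1:b, 1:b] <- config$block_correlation
      diag(sigma)[1:b] <- 1
    }
    u <- stats::rnorm(p_inf)
    u <- u / sqrt(sum(u^2))
    ev <- eigen(sigma, symmetric = TRUE)
    sqrt_sigma <- ev$vectors %*% (sqrt(ev$values) * t(ev$vectors))
    delta <- as.numeric(config$class_separation * sqrt_sigma %*% u)

    x_inf <- rbind(
      MASS::mvrnorm(n0, mu = rep(0, p_inf), Sigma = sigma),
      MASS::mvrnorm(n1, mu = delta, Sigma = sigma))
    x_noise <- matrix(stats::rnorm(n * (p - p_inf)), nrow = n)
    x <- cbind(x_inf, x_noise)

    if (config$outlier_fraction > 0) {
      n_out <- round(config$outlier_fraction * length(x))
      cells <- sample.int(length(x), n_out)
      x[cells] <- x[cells] * config$outlier_scale
    }
    colnames(x) <- sprintf("feature_%02d", seq_len(p))
    out <- as.data.frame(x)
    out$label <- rep(c(0L, 1L), c(n0, n1))
    attr(out, "config") <- config
    out
  })
}

#' Write a synthetic dataset with its config sidecar
#'
#' Writes the labeled CSV and a JSON sidecar recording the full generator
#' configuration (including the seed), so any dataset on disk can be
#' regenerated exactly.
#'
#' @param data Output of [generate_synthetic()].
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.config.json`.
#' @return `path`, invisibly.
#' @export
write_synthetic <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  cfg <- attr(data, "config")
  if (!is.null(cfg)) {
    jsonlite::write_json(unclass(cfg), paste0(path, ".config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
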