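# Shared fixtures and independent oracles, all built in code.

wisconsin_dm <- function() {
  read_decision_matrix(system.file("extdata", "wisconsin_decision_matrix.csv",
                                   package = "prombench"))
}

birads_dm <- function() {
  read_decision_matrix(system.file("extdata", "birads_decision_matrix.csv",
                                   package = "prombench"))
}

# Random decision matrix with random directions, normalized weights and
# explicit positive spreads.
random_dm <- function(n_alt, n_crit, seed) {
  set.seed(seed)
  vals <- matrix(rnorm(n_alt * n_crit, sd = runif(1, 0.5, 20)), n_alt, n_crit,
                 dimnames = list(paste0("alt", seq_len(n_alt)),
                                 paste0("crit", seq_len(n_crit))))
  w <- runif(n_crit)
  crit <- criteria_config(
    name = colnames(vals),
    direction = sample(c("maximize", "minimize"), n_crit, replace = TRUE),
    weight = w / sum(w),
    spread = as.list(runif(n_crit, 0.2, 5)))
  decision_matrix(vals, crit)
}

# Naive triple-loop PROMETHEE flows, independent of the vectorized path.
naive_flows <- function(dm) {
  v <- dm$values
  n <- nrow(v)
  spreads <- vapply(dm$criteria$spread, identity, numeric(1))
  pref <- function(a, b, j) {
    d <- v[a, j] - v[b, j]
    if (dm$criteria$direction[j] == "minimize") d <- -d
    if (d > 0) 1 - exp(-d^2 / (2 * spreads[j]^2)) else 0
  }
  plus <- minus <- numeric(n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      pi_ab <- sum(vapply(seq_along(spreads), function(j) {
        dm$criteria$weight[j] * pref(a, b, j)
      }, numeric(1)))
      plus[a] <- plus[a] + pi_ab
      minus[b] <- minus[b] + pi_ab
    }
  }
  data.frame(alternative = rownames(v),
             phi_plus = plus / (n - 1), phi_minus = minus / (n - 1),
             phi_net = (plus - minus) / (n - 1))
}

# Trapezoid-rule integration of alpha-cut midpoints of a triangular
# membership function: the defining integral behind the Yager index.
yager_oracle <- function(l, m, u, n_grid = 20001) {
  alpha <- seq(0, 1, length.out = n_grid)
  mid <- ((l + alpha * (m - l)) + (u - alpha * (u - m))) / 2
  h <- alpha[2] - alpha[1]
  sum((mid[-1] + mid[-n_grid]) / 2) * h
}

# Small, quick two-class dataset for CV tests.
tiny_dataset <- function(n_per_class = 60, n_features = 6, separation = 3,
                         seed = 11) {
  generate_synthetic(synthetic_config(
    n_class0 = n_per_class, n_class1 = n_per_class, n_features = n_features,
    n_informative = max(2, n_features %/% 2), class_separation = separation,
    correlated_block_size = 2, outlier_fraction = 0, seed = seed))
}
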