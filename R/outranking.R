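#' Criteria configuration table
#'
#' Builds the per-criterion configuration consumed by [decision_matrix()]:
#' name, optimisation direction, a weight (either crisp or via a linguistic
#' label to be defuzzified) and the Gaussian preference spread.
#'
#' @param name Character vector of criterion names (unique).
#' @param direction `"maximize"` or `"minimize"`, recycled if scalar.
#' @param weight Crisp non-negative weights; mutually exclusive with
#'   `weight_label` per criterion (`NA` where a label is given).
#' @param weight_label Linguistic labels resolved through `scale`; `NA` where a
#'   crisp weight is given.
#' @param spread Gaussian spread per criterion: a positive number or the
#'   string `"auto"` (population standard deviation of the criterion column,
#'   resolved when flows are computed).
#' @param scale A [linguistic_scale()] used to defuzzify `weight_label`.
#' @param defuzz_method Passed to [defuzzify()].
#' @return A `data.frame` with columns `name`, `direction`, `weight`
#'   (normalised to sum to 1) and `spread` (list column holding numbers or
#'   `"auto"`), of class `"criteria_config"`.
#' @export
criteria_config <- function(name, direction = "maximize",
                            weight = NULL, weight_label = NULL,
                            spread = "auto",
                            scale = linguistic_scale(),
                            defuzz_method = "yager") {
  J <- length(name)
  stopifnot(J >= 1L, !anyDuplicated(name))
  direction <- rep_len(direction, J)
  if (!all(direction %in% c("maximize", "minimize"))) {
    stop("direction must be 'maximize' or 'minimize'", call. = FALSE)
  }
  if (is.null(weight) && is.null(weight_label)) {
    stop("supply weight or weight_label for every criterion", call. = FALSE)
  }
  if (is.null(weight)) weight <- rep(NA_real_, J)
  if (is.null(weight_label)) weight_label <- rep(NA_character_, J)
  weight <- rep_len(as.numeric(weight), J)
  weight_label <- rep_len(as.character(weight_label), J)
  use_label <- !is.na(weight_label)
  if (any(is.na(weight) & !use_label)) {
    stop("criteria without a weight_label need a numeric weight", call. = FALSE)
  }
  if (any(use_label)) {
    crisp <- vapply(scale[weight_label[use_label]], defuzzify, numeric(1),
                    method = defuzz_method)
    weight[use_label] <- crisp
  }
  if (any(weight < 0)) stop("weights must be non-negative", call. = FALSE)
  spread <- rep_len(as.list(spread), J)
  ok <- vapply(spread, function(s) {
    (is.character(s) && identical(s, "auto")) || (is.numeric(s) && s > 0)
  }, logical(1))
  if (!all(ok)) stop("spread must be a positive number or \"auto\"", call. = FALSE)
  out <- data.frame(name = name, direction = direction,
                    weight = weight / sum(weight),
                    weight_label = weight_label,
                    stringsAsFactors = FALSE)
  out$spread <- spread
  class(out) <- c("criteria_config", "data.frame")
  out
}

#' Decision matrix of alternatives by criteria
#'
#' The performance table feeding the outranking computation: one row per
#' alternative, one column per criterion. Cells must be fully observed;
#' qualitative YES/NO criteria are encoded 1/0 before they reach this
#' constructor (see [encode_qualitative()]).
#'
#' @param values Numeric matrix or data.frame, alternatives in rows, criteria
#'   in columns. Row names (or `alternatives`) name the alternatives.
#' @param criteria A [criteria_config()] whose names match `colnames(values)`.
#' @param alternatives Optional character vector of unique alternative names.
#' @return An object of class `"decision_matrix"`: a list with elements
#'   `values` (numeric matrix) and `criteria`.
#' @export
decision_matrix <- function(values, criteria, alternatives = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(alternatives)) {
    stop("alternatives must be named (row names or `alternatives`)", call. = FALSE)
  }
  rownames(values) <- alternatives
  if (anyDuplicated(alternatives)) {
    stop("alternative names must be unique", call. = FALSE)
  }
  if (nrow(values) < 2L) {
    stop("ranking requires at least two alternatives", call. = FALSE)
  }
  if (!inherits(criteria, "criteria_config")) {
    stop("criteria must be a criteria_config()", call. = FALSE)
  }
  if (is.null(colnames(values))) colnames(values) <- criteria$name
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("missing cell at alternative '%s', criterion '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]),
         call. = FALSE)
  }
  if (!identical(colnames(values), criteria$name)) {
    if (!setequal(colnames(values), criteria$name)) {
      stop("criterion names in `values` and `criteria` disagree", call. = FALSE)
    }
    values <- values[, criteria$name, drop = FALSE]
  }
  structure(list(values = values, criteria = criteria),
            class = "decision_matrix")
}

#' @export
print.decision_matrix <- function(x, ...) {
  cat(sprintf("Decision matrix: %d alternatives x %d criteria\n",
              nrow(x$values), ncol(x$values)))
  dirs <- ifelse(x$criteria$direction == "maximize", "max", "min")
  cat("Directions:", paste(sprintf("%s(%s)", x$criteria$name, dirs), collapse = ", "), "\n")
  print(round(x$values, 4))
  invisible(x)
}

#' @rdname decision_matrix
#' @param x A `decision_matrix`.
#' @export
alternatives <- function(x) rownames(x$values)

#' Pairwise deviation on one criterion
#'
#' Signed advantage of alternative `a` over `b` on criterion `j`:
#' \eqn{g_j(a) - g_j(b)} for a maximize criterion and \eqn{g_j(b) - g_j(a)}
#' for a minimize criterion, so positive deviations always mean "a is better".
#'
#' @param dm A [decision_matrix()].
#' @param a,b Alternative names (or indices).
#' @param j Criterion name (or index).
#' @return A single numeric deviation.
#' @export
deviation <- function(dm, a, b, j) {
  v <- dm$values
  look <- function(key, pool, what) {
    if (is.character(key) && !key %in% pool) {
      stop(sprintf("unknown %s '%s'", what, key), call. = FALSE)
    }
    key
  }
  a <- look(a, rownames(v), "alternative")
  b <- look(b, rownames(v), "alternative")
  j <- look(j, colnames(v), "criterion")
  d <- v[a, j] - v[b, j]
  jj <- if (is.character(j)) match(j, dm$criteria$name) else j
  if (dm$criteria$direction[jj] == "minimize") d <- -d
  unname(d)
}

#' Gaussian preference function
#'
#' Maps a pairwise deviation to a preference degree: 0 for `d <= 0`, and
#' \eqn{1 - \exp(-d^2 / (2 s^2))} for `d > 0`. The Gaussian shape damps small
#' deviations so near-ties generate almost no preference.
#'
#' @param d Numeric deviation(s), in the criterion's own units.
#' @param s Positive spread parameter, same units as `d`.
#' @return Preference degree(s) in `[0, 1)`.
#' @examples
#' gaussian_preference(1, 1)   # 1 - exp(-1/2)
#' @export
gaussian_preference <- function(d, s) {
  if (!is.numeric(s) || any(s <= 0)) {
    stop("Gaussian preference spread s must be > 0", call. = FALSE)
  }
  ifelse(d > 0, 1 - exp(-d^2 / (2 * s^2)), 0)
}

# Resolve "auto" spreads to numbers: population sd of the criterion column,
# falling back to half the column range, and for a constant column (inert
# criterion: every deviation is 0) to 1 with a warning.
resolve_spreads <- function(dm) {
  v <- dm$values
  vapply(seq_len(ncol(v)), function(j) {
    s <- dm$criteria$spread[[j]]
    if (is.numeric(s)) return(s)
    x <- v[, j]
    sd_pop <- sqrt(mean((x - mean(x))^2))
    if (sd_pop > 0) return(sd_pop)
    half_range <- diff(range(x)) / 2
    if (half_range > 0) return(half_range)
    warning(sprintf("criterion '%s' is constant and cannot discriminate (inert)",
                    dm$criteria$name[j]), call. = FALSE)
    1
  }, numeric(1))
}

# Per-criterion preference matrices P_j(a, b), diag 0, as an n x n x J array.
preference_array <- function(dm, spreads = resolve_spreads(dm)) {
  v <- dm$values
  n <- nrow(v)
  J <- ncol(v)
  P <- array(0, dim = c(n, n, J),
             dimnames = list(rownames(v), rownames(v), colnames(v)))
  for (j in seq_len(J)) {
    D <- outer(v[, j], v[, j], "-")
    if (dm$criteria$direction[j] == "minimize") D <- -D
    P[, , j] <- gaussian_preference(D, spreads[j])
  }
  P
}

#' Aggregated preference index
#'
#' Weighted sum over criteria of the Gaussian preference degrees:
#' \eqn{\pi(a, b) = \sum_j w_j P_j(d_j(a, b))}, a number in `[0, 1]` because
#' the weights sum to 1.
#'
#' @inheritParams deviation
#' @return \eqn{\pi(a, b)}.
#' @export
preference_index <- function(dm, a, b) {
  P <- preference_array(dm)
  w <- dm$criteria$weight
  sum(w * P[a, b, ])
}

#' PROMETHEE II outranking flows
#'
#' Computes, for every alternative, the positive flow
#' \eqn{\Phi^+(a) = \frac{1}{n-1}\sum_{b \ne a} \pi(a, b)}, the negative flow
#' \eqn{\Phi^-(a) = \frac{1}{n-1}\sum_{b \ne a} \pi(b, a)}, the net flow
#' \eqn{\Phi = \Phi^+ - \Phi^-}, and the unicriterion net flows
#' \eqn{\phi_j(a) = \frac{1}{n-1}\sum_{b \ne a} [P_j(a,b) - P_j(b,a)]}.
#' The identity \eqn{\Phi(a) = \sum_j w_j \phi_j(a)} makes the per-criterion
#' contributions \eqn{w_j \phi_j(a)} an exact decomposition of the net flow —
#' the segments of the rainbow diagram.
#'
#' @param dm A [decision_matrix()] with at least two alternatives.
#' @param verbose If `TRUE` (default), report the resolved Gaussian spreads
#'   via [message()]; they are the main hidden degree of freedom of the
#'   procedure.
#' @return An object of class `"flow_table"`: list with `flows` (data.frame:
#'   `alternative`, `phi_plus`, `phi_minus`, `phi_net`), `unicriterion`
#'   (alternatives x criteria matrix of \eqn{\phi_j(a)}), `weights` and
#'   `spreads`.
#' @export
compute_flows <- function(dm, verbose = TRUE) {
  if (!inherits(dm, "decision_matrix")) stop("dm must be a decision_matrix")
  n <- nrow(dm$values)
  if (n < 2L) stop("ranking requires at least two alternatives", call. = FALSE)
  spreads <- resolve_spreads(dm)
  names(spreads) <- dm$criteria$name
  if (verbose) {
    message("Gaussian spreads: ",
            paste(sprintf("%s=%.4g", names(spreads), spreads), collapse = ", "))
  }
  P <- preference_array(dm, spreads)
  w <- dm$criteria$weight
  uni <- sapply(seq_along(w), function(j) {
    (rowSums(P[, , j]) - colSums(P[, , j])) / (n - 1)
  })
  dimnames(uni) <- list(rownames(dm$values), dm$criteria$name)
  pi_mat <- matrix(0, n, n)
  for (j in seq_along(w)) pi_mat <- pi_mat + w[j] * P[, , j]
  phi_plus <- rowSums(pi_mat) / (n - 1)
  phi_minus <- colSums(pi_mat) / (n - 1)
  structure(list(
    flows = data.frame(alternative = rownames(dm$values),
                       phi_plus = unname(phi_plus),
                       phi_minus = unname(phi_minus),
                       phi_net = unname(phi_plus - phi_minus),
                       stringsAsFactors = FALSE),
    unicriterion = uni,
    weights = stats::setNames(w, dm$criteria$name),
    spreads = spreads),
    class = "flow_table")
}

#' @export
print.flow_table <- function(x, ...) {
  cat("PROMETHEE II flows\n")
  df <- x$flows
  df[-1] <- lapply(df[-1], round, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Complete ranking by net flow
#'
#' Orders the alternatives by decreasing net flow; ties are broken
#' alphabetically by alternative name so the ranking is deterministic.
#'
#' @param flows A `flow_table` from [compute_flows()].
#' @return data.frame with columns `rank`, `alternative`, `phi_plus`,
#'   `phi_minus`, `phi_net`, one row per alternative, ranks `1..n`.
#' @export
rank_complete <- function(flows) {
  df <- flows$flows
  ord <- order(-df$phi_net, df$alternative)
  out <- df[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Per-criterion net-flow contributions
#'
#' The weighted unicriterion flows \eqn{w_j \phi_j(a)}; each row sums to the
#' alternative's net flow. These are the stacked segments of the rainbow
#' diagram: positive segments are the criteria on which an alternative beats
#' the field, negative segments where it is beaten.
#'
#' @param flows A `flow_table`.
#' @return Alternatives x criteria numeric matrix.
#' @export
flow_contributions <- function(flows) {
  sweep(flows$unicriterion, 2, flows$weights, `*`)
}
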