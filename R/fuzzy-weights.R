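#' Triangular fuzzy number
#'
#' Constructs a triangular fuzzy number (TFN) \eqn{(l, m, u)}: membership rises
#' linearly from the lower support `l` to 1 at the mode `m` and falls linearly
#' to 0 at the upper support `u`. The degenerate case \eqn{l = m = u} is a
#' crisp number. When TFNs encode linguistic criterion importances all three
#' components lie in \eqn{[0, 1]}.
#'
#' @param l Lower support.
#' @param m Mode.
#' @param u Upper support. Must satisfy `l <= m <= u`.
#' @return An object of class `"tfn"`.
#' @examples
#' tfn(0.75, 1, 1)       # the "Very High" importance
#' tfn(0.5, 0.5, 0.5)    # a crisp 0.5
#' @export
tfn <- function(l, m, u) {
  stopifnot(is.numeric(l), is.numeric(m), is.numeric(u),
            length(l) == 1L, length(m) == 1L, length(u) == 1L)
  if (is.na(l) || is.na(m) || is.na(u) || l > m || m > u) {
    stop(sprintf("malformed triangular fuzzy number (%s, %s, %s): need l <= m <= u",
                 format(l), format(m), format(u)), call. = FALSE)
  }
  structure(list(l = l, m = m, u = u), class = "tfn")
}

#' @export
print.tfn <- function(x, ...) {
  cat(sprintf("TFN (%g, %g, %g)\n", x$l, x$m, x$u))
  invisible(x)
}

#' Defuzzify a triangular fuzzy number
#'
#' Collapses a TFN to a crisp representative. The default `"yager"` index is
#' the integral over \eqn{\alpha \in [0, 1]} of the midpoints of the
#' \eqn{\alpha}-cuts, which for a triangular number has the closed form
#' \eqn{(l + 2m + u)/4}. The `"centroid"` alternative is \eqn{(l + m + u)/3}.
#'
#' @param x A [tfn()].
#' @param method `"yager"` (alpha-cut midpoint integral, default) or
#'   `"centroid"`.
#' @return A single numeric value, always inside `[l, u]`.
#' @examples
#' defuzzify(tfn(0.75, 1, 1))            # 0.9375
#' defuzzify(tfn(0.25, 0.5, 0.75))       # 0.5 (symmetric triangle -> mode)
#' @export
defuzzify <- function(x, method = c("yager", "centroid")) {
  if (!inherits(x, "tfn")) x <- do.call(tfn, as.list(unname(unlist(x))[1:3]))
  method <- match.arg(method)
  switch(method,
         yager    = (x$l + 2 * x$m + x$u) / 4,
         centroid = (x$l + x$m + x$u) / 3)
}

#' Linguistic importance scale
#'
#' The five-label scale mapping linguistic importances to triangular fuzzy
#' numbers:
#'
#' | label     | TFN                |
#' |-----------|--------------------|
#' | Very High | (0.75, 1, 1)       |
#' | High      | (0.50, 0.75, 1)    |
#' | Medium    | (0.25, 0.50, 0.75) |
#' | Low       | (0, 0.25, 0.50)    |
#' | Very Low  | (0, 0, 0.25)       |
#'
#' Defuzzified values are strictly decreasing from Very High to Very Low,
#' which the constructor asserts.
#'
#' @param mapping Optional named list of [tfn()]s replacing the default scale;
#'   must contain exactly the five labels above.
#' @return A named list of `tfn` objects with class `"linguistic_scale"`.
#' @export
linguistic_scale <- function(mapping = NULL) {
  if (is.null(mapping)) {
    mapping <- list(
      "Very High" = tfn(0.75, 1.00, 1.00),
      "High"      = tfn(0.50, 0.75, 1.00),
      "Medium"    = tfn(0.25, 0.50, 0.75),
      "Low"       = tfn(0.00, 0.25, 0.50),
      "Very Low"  = tfn(0.00, 0.00, 0.25))
  }
  expected <- c("Very High", "High", "Medium", "Low", "Very Low")
  if (!setequal(names(mapping), expected) || length(mapping) != 5L) {
    stop("a linguistic scale must define exactly the labels: ",
         paste(expected, collapse = ", "), call. = FALSE)
  }
  mapping <- mapping[expected]
  vals <- vapply(mapping, defuzzify, numeric(1))
  if (any(diff(vals) >= 0)) {
    stop("defuzzified scale values must be strictly decreasing from Very High to Very Low",
         call. = FALSE)
  }
  structure(mapping, class = "linguistic_scale")
}

#' Crisp criterion weights from linguistic labels
#'
#' Defuzzifies each criterion's linguistic importance label and normalises by
#' the total, so the weights sum to 1 and keep the input order.
#'
#' @param labels Character vector of scale labels, one per criterion; names, if
#'   present, are carried to the result.
#' @param scale A [linguistic_scale()].
#' @param method Defuzzification method passed to [defuzzify()].
#' @return Named numeric weight vector summing to 1.
#' @examples
#' weights_from_linguistic(c(a = "High", b = "High"))   # 0.5, 0.5
#' @export
weights_from_linguistic <- function(labels, scale = linguistic_scale(),
                                    method = c("yager", "centroid")) {
  method <- match.arg(method)
  stopifnot(length(labels) >= 1L)
  unknown <- setdiff(unique(labels), names(scale))
  if (length(unknown)) {
    stop("unknown linguistic label(s): ", paste(unknown, collapse = ", "),
         "; valid labels are: ", paste(names(scale), collapse = ", "),
         call. = FALSE)
  }
  crisp <- vapply(scale, defuzzify, numeric(1), method = method)[labels]
  w <- as.numeric(crisp) / sum(crisp)
  names(w) <- names(labels)
  w
}
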