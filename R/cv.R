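#' Stratified fold assignment
#'
#' Deals the samples of each class round-robin over `k` folds after a seeded
#' shuffle, so every fold holds (up to rounding) the same class proportions as
#' the full data.
#'
#' @param labels Vector of class labels.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; the assignment is a pure function of
#'   `(labels, k, seed)`.
#' @return Integer vector of fold ids in `1..k`, one per sample.
#' @export
stratified_folds <- function(labels, k = 10, seed = 42) {
  stopifnot(k >= 2)
  tab <- table(labels)
  if (length(tab) < 2L) stop("dataset must contain both classes", call. = FALSE)
  if (any(tab < k)) {
    stop(sprintf("class '%s' has %d members, fewer than %d folds; use fewer folds",
                 names(tab)[which.min(tab)], min(tab), k), call. = FALSE)
  }
  fold <- integer(length(labels))
  withr_seed(seed, {
    for (cls in names(tab)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Evaluate an expression under a temporary RNG state.
withr_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Model families
#'
#' The five supported classifier families and the default hyperparameter grid
#' searched for each: `k` in 1..41 for k-nearest neighbour, RBF-kernel cost
#' `C` in \{0.1, 1, 10, 100\} for the support vector machine, `ntree` in
#' \{5, 10, 50, 100\} for the random forest; logistic regression and naive
#' Bayes run at their defaults (a single grid point).
#'
#' @return `model_families()`: character vector of family names.
#' @export
model_families <- function() {
  c("svm", "random_forest", "logistic_regression", "knn", "naive_bayes")
}

#' @rdname model_families
#' @param family One of `model_families()`.
#' @export
default_grid <- function(family) {
  family <- match.arg(family, model_families())
  switch(family,
    knn = lapply(1:41, function(k) list(k = k)),
    svm = lapply(c(0.1, 1, 10, 100), function(C) list(cost = C, kernel = "radial")),
    random_forest = lapply(c(5, 10, 50, 100), function(n) list(ntree = n)),
    logistic_regression = list(list()),
    naive_bayes = list(list()))
}

# Fit one family on preprocessed features x (matrix) and 0/1 labels y, and
# return a closure mapping new rows to list(prob = P(y = 1), label = 0/1).
# Hard labels come from each model's native decision rule (SVM decision
# boundary, forest majority vote, k-nearest vote, posterior argmax);
# probabilities feed ROC-AUC and log loss only. knn is a lazy learner: the
# "fit" just captures the training set.
fit_model <- function(family, params, x, y) {
  yf <- factor(y, levels = c(0, 1))
  switch(family,
    svm = {
      m <- e1071::svm(x, yf, kernel = params$kernel %||% "radial",
                      cost = params$cost %||% 1, probability = TRUE)
      function(newx) {
        pred <- stats::predict(m, newx, probability = TRUE)
        list(prob = unname(attr(pred, "probabilities")[, "1"]),
             label = as.integer(as.character(pred)))
      }
    },
    random_forest = {
      m <- randomForest::randomForest(x, yf, ntree = params$ntree %||% 100)
      function(newx) {
        pr <- unname(stats::predict(m, newx, type = "prob")[, "1"])
        list(prob = pr, label = as.integer(pr >= 0.5))
      }
    },
    logistic_regression = {
      df <- as.data.frame(x)
      df$.y <- yf
      m <- suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
      function(newx) {
        pr <- unname(suppressWarnings(
          stats::predict(m, as.data.frame(newx), type = "response")))
        list(prob = pr, label = as.integer(pr >= 0.5))
      }
    },
    knn = {
      k <- params$k %||% 5
      function(newx) {
        pred <- class::knn(x, newx, yf, k = k, prob = TRUE)
        p <- attr(pred, "prob")
        list(prob = ifelse(pred == "1", p, 1 - p),
             label = as.integer(as.character(pred)))
      }
    },
    naive_bayes = {
      m <- e1071::naiveBayes(as.data.frame(x), yf)
      function(newx) {
        pr <- unname(stats::predict(m, as.data.frame(newx), type = "raw")[, "1"])
        list(prob = pr, label = as.integer(pr >= 0.5))
      }
    },
    stop("unknown model family: ", family, call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-validated evaluation of one classifier
#'
#' Runs stratified k-fold cross-validation with the full preprocessing
#' pipeline — Tukey-fence winsorisation, standardisation and PCA — fitted on
#' the training folds only and applied to the held-out fold, so no information
#' leaks across the fold boundary. Class probabilities on the held-out fold
#' give ROC-AUC and (negative) log loss; thresholding at 0.5 gives the
#' confusion-matrix metrics.
#'
#' @param data data.frame with numeric feature columns and a 0/1 column named
#'   `label` (0 = negative/benign, 1 = positive/malignant).
#' @param family One of [model_families()].
#' @param params Named list of hyperparameters for the family (see
#'   [default_grid()]); empty list = family defaults.
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed controlling fold assignment and any stochastic
#'   fitting; identical seeds give identical reports.
#' @param variance_retained PCA explained-variance fraction (default 0.95).
#' @param aggregate `"fold"` (default) averages metrics over folds;
#'   `"pooled"` computes them once from the pooled held-out predictions.
#' @return Object of class `"metrics_report"`: list with the averaged
#'   `accuracy`, `precision`, `recall`, `specificity`, `f1`, `roc_auc`,
#'   `neg_log_loss` (natural log, <= 0), `support`, plus `per_fold`,
#'   `family`, `params`.
#' @export
evaluate_cv <- function(data, family, params = list(), folds = 10, seed = 42,
                        variance_retained = 0.95,
                        aggregate = c("fold", "pooled")) {
  aggregate <- match.arg(aggregate)
  family <- match.arg(family, model_families())
  if (!"label" %in% names(data)) stop("data needs a 'label' column", call. = FALSE)
  y <- data$label
  if (!all(y %in% c(0, 1))) stop("label must be 0/1", call. = FALSE)
  x <- as.matrix(data[setdiff(names(data), "label")])
  if (!is.numeric(x)) stop("feature columns must be numeric", call. = FALSE)
  fold <- stratified_folds(y, k = folds, seed = seed)

  per_fold <- vector("list", folds)
  pooled_prob <- numeric(length(y))
  pooled_label <- integer(length(y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    pre <- preprocess_fit(x[tr, , drop = FALSE], variance_retained)
    xtr <- preprocess_apply(pre, x[tr, , drop = FALSE])
    xte <- preprocess_apply(pre, x[!tr, , drop = FALSE])
    model_predict <- withr_seed(seed * 1000L + f,
                                fit_model(family, params, xtr, y[tr]))
    held_out <- withr_seed(seed * 1000L + f, model_predict(xte))
    prob <- held_out$prob
    pooled_prob[!tr] <- prob
    pooled_label[!tr] <- held_out$label
    truth <- y[!tr]
    pred <- held_out$label
    cm <- confusion_matrix(tp = sum(pred == 1 & truth == 1),
                           tn = sum(pred == 0 & truth == 0),
                           fp = sum(pred == 1 & truth == 0),
                           fn = sum(pred == 0 & truth == 1))
    m <- suppressWarnings(metrics_from_confusion(cm))
    per_fold[[f]] <- data.frame(
      fold = f, accuracy = m$accuracy, precision = m$precision,
      recall = m$recall, specificity = m$specificity, f1 = m$f1,
      roc_auc = score_auc(truth, prob),
      neg_log_loss = neg_log_loss(truth, prob))
  }
  per_fold <- do.call(rbind, per_fold)

  metrics <- if (aggregate == "fold") {
    as.list(colMeans(per_fold[-1], na.rm = TRUE))
  } else {
    pred <- pooled_label
    cm <- confusion_matrix(tp = sum(pred == 1 & y == 1),
                           tn = sum(pred == 0 & y == 0),
                           fp = sum(pred == 1 & y == 0),
                           fn = sum(pred == 0 & y == 1))
    m <- suppressWarnings(metrics_from_confusion(cm))
    list(accuracy = m$accuracy, precision = m$precision, recall = m$recall,
         specificity = m$specificity, f1 = m$f1,
         roc_auc = score_auc(y, pooled_prob),
         neg_log_loss = neg_log_loss(y, pooled_prob))
  }
  structure(c(metrics,
              list(support = c(positive = sum(y == 1), negative = sum(y == 0)),
                   per_fold = per_fold, family = family, params = params,
                   folds = folds, seed = seed, aggregate = aggregate)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("CV metrics for %s (%d-fold, seed %d)\n", x$family, x$folds, x$seed))
  for (m in c("accuracy", "precision", "recall", "specificity", "f1",
              "roc_auc", "neg_log_loss")) {
    cat(sprintf("  %-13s %.4f\n", m, x[[m]]))
  }
  invisible(x)
}

#' Exhaustive grid search over hyperparameters
#'
#' Evaluates every grid entry with [evaluate_cv()] and keeps the one with the
#' highest mean CV accuracy; on ties the first-listed entry wins, so the
#' search is deterministic and idempotent under duplicated entries.
#'
#' @inheritParams evaluate_cv
#' @param grid List of hyperparameter lists; defaults to
#'   [default_grid()] for the family.
#' @return List with `best_params`, `report` (the winning
#'   [evaluate_cv()] report) and `results` (data.frame of mean accuracy per
#'   grid entry).
#' @export
grid_search <- function(data, family, grid = NULL, folds = 10, seed = 42,
                        variance_retained = 0.95) {
  family <- match.arg(family, model_families())
  if (is.null(grid)) grid <- default_grid(family)
  stopifnot(length(grid) >= 1L)
  reports <- lapply(grid, function(params) {
    evaluate_cv(data, family, params, folds = folds, seed = seed,
                variance_retained = variance_retained)
  })
  acc <- vapply(reports, function(r) r$accuracy, numeric(1))
  best <- which.max(acc)  # which.max keeps the first of tied entries
  list(best_params = grid[[best]],
       report = reports[[best]],
       results = data.frame(
         entry = vapply(grid, function(p) {
           if (!length(p)) "default"
           else paste(names(p), unlist(p), sep = "=", collapse = ",")
         }, character(1)),
         accuracy = acc))
}

#' Benchmark the five classifier families
#'
#' Runs [grid_search()] (or a single default fit) for each family and collects
#' the six quantitative criteria — accuracy, recall, precision, F1, ROC-AUC
#' and negative log loss — into one table ready for
#' [assemble_decision_matrix()].
#'
#' @inheritParams evaluate_cv
#' @param families Subset of [model_families()].
#' @param search If `TRUE` (default) grid-search each family; otherwise use
#'   the family defaults.
#' @return data.frame with one row per family (display names such as "SVM"),
#'   columns `model`, `accuracy`, `recall`, `precision`, `f1`, `roc_auc`,
#'   `neg_log_loss` as fractions / raw values, with the chosen hyperparameters
#'   in `attr(, "best_params")`.
#' @export
bench_classifiers <- function(data, families = model_families(), folds = 10,
                              seed = 42, variance_retained = 0.95,
                              search = TRUE) {
  families <- match.arg(families, model_families(), several.ok = TRUE)
  best <- list()
  rows <- lapply(families, function(fam) {
    rep <- if (search) {
      gs <- grid_search(data, fam, folds = folds, seed = seed,
                        variance_retained = variance_retained)
      best[[fam]] <<- gs$best_params
      gs$report
    } else {
      best[[fam]] <<- list()
      evaluate_cv(data, fam, folds = folds, seed = seed,
                  variance_retained = variance_retained)
    }
    data.frame(model = family_display_name(fam),
               accuracy = rep$accuracy, recall = rep$recall,
               precision = rep$precision, f1 = rep$f1,
               roc_auc = rep$roc_auc, neg_log_loss = rep$neg_log_loss,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "best_params") <- best
  out
}

# Display names used in decision matrices and reports.
family_display_name <- function(family) {
  c(svm = "SVM", random_forest = "Random Forest",
    logistic_regression = "Logistic Regression", knn = "KNN",
    naive_bayes = "Naive Bayes")[[family]]
}
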