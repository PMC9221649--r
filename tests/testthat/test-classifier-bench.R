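test_that("Tukey-fence winsorisation replaces outliers with quartile values", {
  expect_equal(winsorize_outliers(c(1, 2, 3, 4, 5)), c(1, 2, 3, 4, 5))
  expect_equal(winsorize_outliers(c(1, 2, 3, 4, 100)), c(1, 2, 3, 4, 4))
  expect_equal(winsorize_outliers(c(5, 5, 5, 5)), c(5, 5, 5, 5))
  expect_equal(winsorize_outliers(c(-100, 2, 3, 4, 5)), c(2, 2, 3, 4, 5))
  expect_error(winsorize_outliers(letters[1:5]), "numeric")
  # fence multiplier is configurable
  x <- c(1, 2, 3, 4, 8)
  expect_equal(winsorize_outliers(x, k = 10), x)
})

test_that("confusion-matrix metrics match hand-computed values", {
  m <- metrics_from_confusion(confusion_matrix(tp = 50, tn = 40, fp = 0, fn = 0))
  expect_equal(unlist(m[c("accuracy", "precision", "recall", "specificity", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, specificity = 1, f1 = 1))

  m <- metrics_from_confusion(confusion_matrix(tp = 40, tn = 30, fp = 20, fn = 10))
  expect_equal(m$accuracy, 0.70)
  expect_equal(m$precision, 2 / 3, tolerance = 1e-9)
  expect_equal(m$recall, 0.80)
  expect_equal(m$specificity, 0.60)
  expect_equal(m$f1, 8 / 11, tolerance = 1e-9)
  expect_equal(m$support, c(positive = 50, negative = 50))

  w <- capture_warnings(m0 <- metrics_from_confusion(confusion_matrix(0, 10, 0, 5)))
  expect_match(w, "precision is undefined", all = FALSE)
  expect_match(w, "f1 is undefined", all = FALSE)  # cascades from precision
  expect_true(is.na(m0$precision))
  expect_true(is.na(m0$f1))
  expect_error(confusion_matrix(-1, 2, 3, 4), "non-negative")
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(801)
  for (i in 1:30) {
    cm <- confusion_matrix(tp = sample(1:80, 1), tn = sample(1:80, 1),
                           fp = sample(1:80, 1), fn = sample(1:80, 1))
    m <- metrics_from_confusion(cm)
    n <- cm$tp + cm$tn + cm$fp + cm$fn
    expect_equal(m$accuracy * n, cm$tp + cm$tn)
    expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall),
                 tolerance = 1e-9)
    fpr <- cm$fp / (cm$fp + cm$tn)
    expect_equal(m$specificity + fpr, 1, tolerance = 1e-12)
    expect_true(all(unlist(m[c("accuracy", "precision", "recall",
                               "specificity", "f1")]) >= 0))
    expect_true(all(unlist(m[c("accuracy", "precision", "recall",
                               "specificity", "f1")]) <= 1))
  }
})

test_that("PCA keeps the fewest components reaching the variance target", {
  # exact rank-2 structure in 5 dimensions
  set.seed(802)
  basis <- matrix(rnorm(10), 5, 2)
  x2 <- matrix(rnorm(160), 80, 2) %*% t(basis)
  expect_equal(pca_reduce(x2, 0.99)$n_components, 2)

  # full variance keeps everything up to rank
  xf <- matrix(rnorm(200 * 6), 200, 6)
  fit <- pca_reduce(xf, 1.0)
  expect_equal(fit$n_components, 6)
  recon <- fit$scores %*% t(fit$rotation)
  expect_equal(recon, sweep(xf, 2, fit$center), tolerance = 1e-9)

  # component count agrees with an independent eigendecomposition oracle
  xi <- matrix(rnorm(100 * 30), 100, 30)
  for (target in c(0.5, 0.8, 0.95)) {
    ev <- eigen(stats::cov(xi), symmetric = TRUE, only.values = TRUE)$values
    oracle <- which(cumsum(ev) / sum(ev) >= target - 1e-12)[1]
    expect_equal(pca_reduce(xi, target)$n_components, oracle)
  }

  # held-out projection reuses the fitted transform
  fit <- pca_reduce(xf[1:150, ], 0.9)
  proj <- pca_apply(fit, xf[151:200, ])
  expect_equal(dim(proj), c(50, fit$n_components))
})

test_that("stratified folds preserve class proportions and are seeded", {
  y <- rep(c(0, 1), c(70, 30))
  f1 <- stratified_folds(y, k = 5, seed = 3)
  f2 <- stratified_folds(y, k = 5, seed = 3)
  expect_identical(f1, f2)
  expect_false(identical(f1, stratified_folds(y, k = 5, seed = 4)))
  for (k in 1:5) {
    expect_equal(sum(y[f1 == k] == 1), 6)  # 30/5 positives per fold
    expect_equal(sum(y[f1 == k] == 0), 14)
  }
  expect_error(stratified_folds(rep(c(0, 1), c(50, 3)), k = 5), "fewer folds")
  expect_error(stratified_folds(rep(0, 20), k = 5), "both classes")
})

test_that("cross-validated evaluation is deterministic under a fixed seed", {
  d <- tiny_dataset()
  r1 <- evaluate_cv(d, "logistic_regression", folds = 5, seed = 9)
  r2 <- evaluate_cv(d, "logistic_regression", folds = 5, seed = 9)
  expect_identical(r1[c("accuracy", "roc_auc", "neg_log_loss")],
                   r2[c("accuracy", "roc_auc", "neg_log_loss")])
  expect_identical(r1$per_fold, r2$per_fold)
  expect_lte(r1$neg_log_loss, 0)
  expect_true(r1$roc_auc >= 0 && r1$roc_auc <= 1)
})

test_that("well-separated classes are learned nearly perfectly by every family", {
  d <- tiny_dataset(n_per_class = 60, separation = 12, seed = 21)
  for (fam in model_families()) {
    r <- evaluate_cv(d, fam, folds = 5, seed = 5)
    expect_gte(r$accuracy, 0.99)
  }
})

test_that("permuted labels give chance-level discrimination", {
  d <- tiny_dataset(n_per_class = 50, separation = 3, seed = 31)
  aucs <- sapply(1:6, function(i) {
    set.seed(900 + i)
    d$label <- sample(d$label)
    evaluate_cv(d, "logistic_regression", folds = 5, seed = 900 + i)$roc_auc
  })
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("fold-wise preprocessing differs from a leaky whole-data fit", {
  d <- tiny_dataset(n_per_class = 40, n_features = 8, separation = 1.5, seed = 41)
  honest <- evaluate_cv(d, "knn", params = list(k = 7), folds = 5, seed = 6)

  # leaky variant: preprocessing fitted once on all rows, then CV on the
  # transformed features with no further preprocessing possible to undo it
  x <- as.matrix(d[setdiff(names(d), "label")])
  pre <- prombench:::preprocess_fit(x, 0.95)
  leaked <- as.data.frame(prombench:::preprocess_apply(pre, x))
  leaked$label <- d$label
  fold <- stratified_folds(d$label, 5, seed = 6)
  accs <- sapply(1:5, function(f) {
    model_predict <- prombench:::fit_model("knn", list(k = 7),
                                           as.matrix(leaked[fold != f, -ncol(leaked)]),
                                           leaked$label[fold != f])
    mean(model_predict(as.matrix(leaked[fold == f, -ncol(leaked)]))$label ==
           leaked$label[fold == f])
  })
  expect_false(isTRUE(all.equal(honest$accuracy, mean(accs))))
})

test_that("grid search is exhaustive, deterministic and idempotent", {
  d <- tiny_dataset(n_per_class = 40, seed = 51)
  g1 <- grid_search(d, "knn", grid = list(list(k = 5)), folds = 4, seed = 2)
  expect_equal(g1$best_params, list(k = 5))  # degenerate grid

  dup <- grid_search(d, "knn", grid = list(list(k = 3), list(k = 7), list(k = 3)),
                     folds = 4, seed = 2)
  dedup <- grid_search(d, "knn", grid = list(list(k = 3), list(k = 7)),
                       folds = 4, seed = 2)
  expect_equal(dup$best_params, dedup$best_params)
  expect_equal(dup$report$accuracy, dedup$report$accuracy)
})

test_that("an RBF SVM beats linear logistic regression on a spherical boundary", {
  set.seed(61)
  n <- 260
  x <- matrix(rnorm(n * 2), n, 2)
  r <- sqrt(rowSums(x^2))
  d <- data.frame(x, label = as.integer(r < stats::median(r)))
  names(d)[1:2] <- c("feature_01", "feature_02")
  svm_acc <- grid_search(d, "svm", grid = list(list(cost = 1), list(cost = 10)),
                         folds = 5, seed = 3)$report$accuracy
  lr_acc <- evaluate_cv(d, "logistic_regression", folds = 5, seed = 3)$accuracy
  expect_gt(svm_acc, lr_acc)
})

test_that("the default grids match the documented search spaces", {
  expect_length(default_grid("knn"), 41)
  expect_equal(default_grid("knn")[[14]]$k, 14)
  expect_equal(vapply(default_grid("svm"), `[[`, numeric(1), "cost"),
               c(0.1, 1, 10, 100))
  expect_equal(vapply(default_grid("random_forest"), `[[`, numeric(1), "ntree"),
               c(5, 10, 50, 100))
  expect_length(default_grid("logistic_regression"), 1)
  expect_length(default_grid("naive_bayes"), 1)
})
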