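test_that("confusion metrics follow the four definitions exactly", {
  m <- compute_metrics(c(TP = 3, TN = 5, FP = 1, FN = 1))
  expect_equal(m, list(accuracy = 0.8, precision = 0.75, recall = 0.75,
                       f1 = 0.75))
  perfect <- compute_metrics(c(TP = 4, TN = 6, FP = 0, FN = 0))
  expect_true(all(unlist(perfect) == 1))
  degen <- compute_metrics(c(TP = 0, TN = 5, FP = 3, FN = 2))
  expect_equal(degen$precision, 0)
  expect_equal(degen$f1, 0)
  expect_error(compute_metrics(c(TP = 0, TN = 0, FP = 0, FN = 0)), "no eval")
})

test_that("confusion counts partition the evaluated samples", {
  set.seed(41)
  truth <- sample(c("FBTP", "NFBTP"), 50, replace = TRUE)
  pred <- sample(c("FBTP", "NFBTP"), 50, replace = TRUE)
  cc <- confusion_counts(truth, pred)
  expect_equal(sum(cc), 50)
  expect_equal(cc[["TP"]], sum(truth == "FBTP" & pred == "FBTP"))
})

test_that("LOOCV pooling reproduces a hand-traced 1-nearest-neighbor run", {
  # 4 points on a line: 0, 1, 10, 11; labels F F N N. Leaving each out,
  # 1-NN predicts F F N N (each point's nearest neighbor shares its label).
  x <- c(0, 1, 10, 11)
  truth <- c("FBTP", "FBTP", "NFBTP", "NFBTP")
  pred <- vapply(1:4, function(i) {
    truth[-i][which.min(abs(x[-i] - x[i]))]
  }, character(1))
  expect_equal(pred, truth)
  expect_equal(compute_metrics(confusion_counts(truth, pred))$accuracy, 1)
  # a contaminating point flips exactly itself: 0, 8.9, 10, 11 / F N N N
  x2 <- c(0, 8.9, 10, 11)
  truth2 <- c("FBTP", "FBTP", "NFBTP", "NFBTP")
  pred2 <- vapply(1:4, function(i) {
    truth2[-i][which.min(abs(x2[-i] - x2[i]))]
  }, character(1))
  expect_equal(pred2, c("FBTP", "NFBTP", "NFBTP", "NFBTP"))
  expect_equal(compute_metrics(confusion_counts(truth2, pred2))$recall, 0.5)
})

test_that("LOOCV produces n size-1 folds whose pooled metrics recompute", {
  tab <- make_kind_split_table(n1 = 11, n2 = 14, seed = 51)
  spec <- stacked_model_spec(c("xc", "xd", "xb"), seed = 51)
  cv <- loocv_evaluate(tab, spec = spec)
  expect_equal(nrow(cv$folds), 25)
  expect_equal(sort(cv$folds$row), 1:25)
  expect_equal(unname(table(cv$folds$fold)), rep(1L, 25),
               ignore_attr = TRUE)
  recomputed <- compute_metrics(confusion_counts(cv$folds$truth,
                                                 cv$folds$pred))
  expect_equal(cv$metrics, recomputed)
})

test_that("a continuous-only spec degenerates to Gaussian NB under the meta", {
  tab <- make_kind_split_table(n1 = 30, n2 = 30, seed = 3)
  m <- fit_stacked(tab, spec = stacked_model_spec(c("xc", "noise"), seed = 3))
  expect_named(m$fits, "gaussian")
  pr <- predict(m, tab)
  expect_equal(nrow(pr), 60)
  expect_s3_class(pr$label, "factor")
})

test_that("stacking performs at least as well as its best base learner (within 0.05)", {
  train <- make_kind_split_table(n1 = 100, n2 = 100, seed = 8)
  test <- make_kind_split_table(n1 = 200, n2 = 200, seed = 9)
  spec <- stacked_model_spec(c("xc", "xd", "xb"), seed = 8)
  m <- fit_stacked(train, spec = spec)
  stacked_acc <- mean(predict(m, test)$label == test$labels)
  base_acc <- vapply(names(m$fits), function(nm) {
    kind <- switch(nm, gaussian = "continuous", multinomial = "discrete",
                   bernoulli = "binary")
    cols <- features_of_kind(train, kind)
    cols <- intersect(cols, c("xc", "xd", "xb"))
    prep <- rltstack:::fit_preprocessor(
      train$data, train$specs[match(cols, train$specs$name), ],
      seq_len(nrow(train$data)))
    Xte <- rltstack:::apply_preprocessor(prep, test$data,
                                         seq_len(nrow(test$data)))
    p <- predict(m$fits[[nm]], Xte)
    mean(ifelse(p[, "FBTP"] >= 0.5, "FBTP", "NFBTP") == test$labels)
  }, numeric(1))
  expect_gte(stacked_acc, max(base_acc) - 0.05)
})

test_that("permuted labels cap the stacked model at chance (no-information bound)", {
  # LOOCV under a destroyed association must not exceed chance beyond its
  # binomial CI; below-chance results are the known pessimistic LOOCV bias
  # and are acceptable.
  set.seed(61)
  tab <- make_kind_split_table(n1 = 20, n2 = 20, seed = 61)
  perm <- feature_table(tab$data, tab$specs,
                        sample(tab$labels)) # break the association
  cv <- suppressWarnings(
    loocv_evaluate(perm, spec = stacked_model_spec(c("xc", "xd", "xb"),
                                                   seed = 61)))
  expect_lte(cv$metrics$accuracy, 0.5 + 2 * sqrt(0.25 / 40))
})

test_that("the baseline battery is deterministic and beats 0.8 when separable", {
  set.seed(71)
  n <- 100
  y <- rep(c("FBTP", "NFBTP"), each = n)
  data <- data.frame(f1 = rnorm(2 * n, ifelse(y == "FBTP", 1.5, 0)),
                     f2 = rnorm(2 * n, ifelse(y == "FBTP", 0, 1.5)),
                     f3 = rnorm(2 * n))
  tab <- feature_table(data, feature_spec(names(data), "continuous"),
                       factor(y, levels = c("FBTP", "NFBTP")))
  res <- compare_baselines(tab, k = 5, seed = 5)
  expect_setequal(res$model,
                  c("logistic", "random_forest", "xgboost", "decision_tree",
                    "knn", "svm", "naive_bayes"))
  expect_true(all(res$accuracy > 0.8))
  res2 <- compare_baselines(tab, k = 5, seed = 5)
  expect_identical(res, res2)
  expect_identical(attr(res, "folds")$fold, attr(res2, "folds")$fold)
})

test_that("the grid search honors precision-first selection and tie-breaks", {
  tab <- make_kind_split_table(n1 = 12, n2 = 13, seed = 81)
  gs <- grid_search_config(tab, ordered_features = c("xc", "xb", "xd"),
                           feature_budget = 3,
                           meta_options = "logistic", seed = 81)
  expect_equal(nrow(gs$scan), 3)
  ord <- gs$scan[order(-gs$scan$precision, -gs$scan$accuracy,
                       gs$scan$n_features), ]
  expect_equal(length(gs$best_spec$features), ord$n_features[1])
  # singleton scan returns unconditionally
  gs1 <- grid_search_config(tab, ordered_features = "xc",
                            feature_budget = 1, meta_options = "logistic",
                            seed = 81)
  expect_equal(gs1$best_spec$features, "xc")
  expect_error(grid_search_config(tab, ordered_features = character(0)),
               "empty")
})
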