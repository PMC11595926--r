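test_that("Spearman rho follows the rank-difference formula", {
  expect_equal(spearman_score(1:4, c(1, 3, 2, 4)), 0.8)
  expect_equal(spearman_score(c(2, 5, 9), c(1, 2, 3)), 1)
  expect_equal(spearman_score(c(9, 5, 2), c(1, 2, 3)), -1)
  expect_warning(s <- spearman_score(rep(1, 5), c(0, 1, 0, 1, 0)),
                 "constant")
  expect_equal(s, 0)
})

test_that("point-biserial implements the printed and textbook denominators", {
  y <- factor(c("a", "a", "b", "b"))
  expect_equal(point_biserial_score(c(2, 2, 0, 0), y), 2 / sqrt(3),
               tolerance = 1e-9) # 1.1547, printed n(n-1) form
  expect_equal(point_biserial_score(c(2, 2, 0, 0), y, form = "textbook"), 1)
  expect_equal(point_biserial_score(c(1, 3, 3, 1), y), 0) # equal means
  set.seed(1)
  x <- rnorm(30)
  y2 <- factor(rep(c("a", "b"), 15))
  y2_swap <- factor(rep(c("a", "b"), 15), levels = c("b", "a"))
  expect_equal(point_biserial_score(x, y2), -point_biserial_score(x, y2_swap))
})

test_that("multivariable logistic importance finds the informative feature", {
  set.seed(9)
  n <- 300
  X <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("f", 1:5)))
  y <- as.integer(X[, "f3"] + rnorm(n, sd = 0.5) > 0)
  sc <- bcrac_score(scale(X), y)
  expect_equal(names(which.max(sc)), "f3")
  # pure-noise feature keeps a near-zero weight at large n
  expect_lt(min(sc[c("f1", "f2", "f4", "f5")]), sc[["f3"]] / 5)
  # collinearity: a duplicated column splits weight under the ridge path
  set.seed(10)
  Xs <- matrix(rnorm(8 * 9), 8, dimnames = list(NULL, paste0("g", 1:9)))
  Xs[, 2] <- Xs[, 1] # p + 1 >= n forces the penalized fit
  ys <- as.integer(Xs[, 1] > 0)
  scs <- suppressWarnings(bcrac_score(Xs, ys)) # tiny-n glmnet advisory
  single <- suppressWarnings(bcrac_score(Xs[, -2, drop = FALSE], ys))
  expect_lt(scs[["g1"]], single[["g1"]] + 1e-9)
  expect_lt(scs[["g2"]], single[["g1"]] + 1e-9)
})

test_that("information gain is bounded by the label entropy and exact on toys", {
  y <- rep(c(0, 1), each = 10)
  x_perfect <- y
  expect_equal(information_gain_score(x_perfect, y), 1) # 1 bit
  set.seed(2)
  x_indep <- sample(0:1, 20, replace = TRUE)
  expect_lt(information_gain_score(x_indep, y), 0.3)
  for (i in 1:10) {
    x <- sample(0:3, 20, replace = TRUE)
    ig <- information_gain_score(x, y)
    expect_gte(ig, -1e-12)
    expect_lte(ig, 1 + 1e-12) # H(T) = 1 for balanced binary labels
  }
})

test_that("MRMR penalizes redundancy and reduces to max-MI at k = 1", {
  set.seed(5)
  n <- 200
  y <- rep(0:1, each = n / 2)
  strong <- ifelse(y == 1, 2, 0) + rnorm(n, sd = 0.3)
  X <- data.frame(a_strong = strong, b_copy = strong,
                  c_weak = ifelse(y == 1, 1, 0) + rnorm(n))
  ord <- mrmr_rank(X, y)
  expect_true(ord[1] %in% c("a_strong", "b_copy"))
  expect_equal(ord[2], "c_weak") # the copy is penalized for redundancy
  expect_equal(mrmr_rank(X, y, k = 1), ord[1])
  expect_warning(mrmr_rank(X, y, k = 10), "truncated")
  # IG and MRMR agree on the first pick for any single-informative toy
  ig <- vapply(X, information_gain_score, numeric(1), y = y)
  expect_equal(ord[1], names(which.max(ig)))
})

test_that("RFE ranks a determining feature first and is seed-deterministic", {
  set.seed(12)
  n <- 120
  X <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("f", 1:6)))
  y <- factor(ifelse(X[, "f2"] > 0, "FBTP", "NFBTP"))
  for (kind in c("logistic", "random_forest")) {
    r1 <- wrapper_rfe_rank(X, y, kind, seed = 3, ntree = 100)
    expect_equal(r1[1], "f2")
    expect_setequal(r1, colnames(X))
    r2 <- wrapper_rfe_rank(X, y, kind, seed = 3, ntree = 100)
    expect_identical(r1, r2)
  }
})

test_that("LDA loadings favor the separating direction and survive singular scatter", {
  set.seed(8)
  n <- 100
  X <- cbind(sep = c(rnorm(n, 2), rnorm(n, -2)),
             flat = rnorm(2 * n))
  y <- rep(c("FBTP", "NFBTP"), each = n)
  sc <- lda_score(scale(X), y)
  expect_gt(sc[["sep"]], 5 * sc[["flat"]])
  # cross-check the discriminant direction against MASS::lda
  m <- MASS::lda(scale(X), grouping = y)
  ratio <- sc / abs(m$scaling[, 1])
  expect_equal(unname(ratio[1] / ratio[2]), 1, tolerance = 1e-6)
  # duplicated column: singular within-class scatter, shrinkage applied
  Xd <- cbind(X, dup = X[, 1])
  expect_message(lda_score(scale(Xd), y), "shrinkage")
})

test_that("LASSO shrinks noise to zero and matches the unpenalized limit", {
  set.seed(14)
  n <- 200
  X <- matrix(rnorm(n * 21), n, dimnames = list(NULL, sprintf("f%02d", 1:21)))
  y <- as.integer(X[, "f05"] * 2 + rnorm(n, sd = 0.8) > 0)
  sc <- lasso_score(scale(X), y)
  expect_gt(sc[["f05"]], 0)
  expect_equal(names(which.max(sc)), "f05")
  expect_warning(sc_inf <- lasso_score(scale(X), y, lambda = 1e6),
                 "zero")
  expect_true(all(sc_inf == 0))
  # lambda = 0, gaussian loss: coefficients equal least squares
  sc0 <- lasso_score(scale(X)[, 1:3], y, lambda = 0, family = "gaussian")
  ls <- abs(coef(lm(y ~ scale(X)[, 1:3]))[-1])
  expect_equal(unname(sc0), unname(ls), tolerance = 1e-4)
})

test_that("ranking lists sort by score with alphabetical ties, stably", {
  rl <- ranking_list("m", c(b = 1, a = 1, c = 2))
  expect_equal(rl$features, c("c", "a", "b"))
  expect_true(all(diff(rl$scores) <= 0))
  expect_error(ranking_list("m", c(1, 2)), "named")
})

test_that("continuous lists are truncated to the top 50; categorical never", {
  specs <- feature_spec(c(sprintf("c%02d", 1:60), sprintf("k%02d", 1:8)),
                        c(rep("continuous", 60), rep("discrete", 8)))
  sc <- setNames(seq(68, 1), c(sprintf("c%02d", 1:60), sprintf("k%02d", 1:8)))
  rl <- ranking_list("m", sc)
  tr <- rltstack:::truncate_ranking(rl, specs, max_continuous = 50)
  expect_equal(sum(tr$features %in% sprintf("c%02d", 1:60)), 50)
  expect_equal(sum(tr$features %in% sprintf("k%02d", 1:8)), 8)
  expect_equal(tr$N, 58)
})

test_that("the battery emits seven ranking lists on a mixed cohort", {
  tab <- make_kind_split_table(n1 = 40, n2 = 40, seed = 6)
  rls <- suppressWarnings(suppressMessages(
    build_ranking_lists(tab, seed = 6, ntree = 60)))
  expect_named(rls, c("correlation", "information_gain", "mrmr",
                      "rfe_logistic", "rfe_random_forest", "lda", "lasso"))
  for (rl in rls) {
    expect_s3_class(rl, "ranking_list")
    expect_false(anyDuplicated(rl$features) > 0)
    # the informative continuous feature beats the noise one everywhere
    expect_lt(match("xc", rl$features), match("noise", rl$features))
  }
})
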