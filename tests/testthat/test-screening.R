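test_that("exact Mann-Whitney p matches full enumeration and wilcox.test", {
  expect_equal(mann_whitney_u(c(4, 5, 6), c(1, 2, 3), mode = "exact")$p_value,
               0.1)
  set.seed(42)
  for (n1 in c(2, 4, 6)) {
    for (n2 in c(3, 5, 7)) {
      vals <- sample(seq_len(50), n1 + n2) # tie-free
      g1 <- vals[seq_len(n1)]
      g2 <- vals[-seq_len(n1)]
      mine <- mann_whitney_u(g1, g2, mode = "exact")
      oracle <- mw_exact_oracle(g1, g2)
      expect_equal(mine$statistic, oracle$U)
      expect_equal(mine$p_value, oracle$p)
      # independent library cross-check (W = pairs g1 > g2 = n1*n2 - U)
      wt <- wilcox.test(g1, g2, exact = TRUE)
      expect_equal(n1 * n2 - mine$statistic, unname(wt$statistic))
      expect_equal(mine$p_value, wt$p.value)
    }
  }
})

test_that("U statistic identities hold with and without ties", {
  # midranks put fully tied groups at the distribution's center
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3),
                              mode = "normal")$statistic, 4.5)
  set.seed(7)
  for (i in 1:20) {
    g1 <- sample(0:5, sample(2:8, 1), replace = TRUE)
    g2 <- sample(0:5, sample(2:8, 1), replace = TRUE)
    u12 <- mann_whitney_u(g1, g2, mode = "normal")$statistic
    u21 <- mann_whitney_u(g2, g1, mode = "normal")$statistic
    expect_equal(u12 + u21, length(g1) * length(g2))
  }
  expect_error(mann_whitney_u(c(1, 1, 2), c(2, 3, 4), mode = "exact"),
               "tie-free")
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("normal approximation converges to the exact p at n1 = n2 = 20", {
  set.seed(11)
  for (i in 1:5) {
    vals <- sample(seq_len(1000), 40)
    g1 <- vals[1:20]
    g2 <- vals[21:40]
    pe <- mann_whitney_u(g1, g2, mode = "exact")$p_value
    pn <- mann_whitney_u(g1, g2, mode = "normal")$p_value
    expect_lt(abs(pe - pn), 0.01)
  }
})

test_that("chi-square statistic follows the expected-count formula", {
  even <- chi_square_independence(matrix(c(5, 5, 5, 5), 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)
  diag2 <- suppressWarnings(chi_square_independence(matrix(c(10, 0, 0, 10), 2)))
  expect_equal(diag2$statistic, 20)
  expect_equal(diag2$df, 1)
  tab23 <- matrix(c(7, 7, 3, 4, 1, 3), 2) # 2 x 3, hand value 0.794
  r <- suppressWarnings(chi_square_independence(tab23))
  expect_equal(r$statistic, 0.79429, tolerance = 1e-4)
  expect_equal(r$df, 2)
  expect_equal(sum(r$observed), sum(r$expected))
  # library cross-check, no continuity correction
  ct <- suppressWarnings(chisq.test(tab23, correct = FALSE))
  expect_equal(r$statistic, unname(ct$statistic))
  expect_equal(r$p_value, ct$p.value)
})

test_that("chi-square is permutation invariant and zero iff observed = expected", {
  set.seed(3)
  O <- matrix(rpois(12, 20) + 1, 3, 4)
  base <- chi_square_independence(O)
  perm <- chi_square_independence(O[c(3, 1, 2), c(2, 4, 1, 3)])
  expect_equal(base$statistic, perm$statistic)
  indep <- outer(c(10, 20), c(5, 15)) / 25 # rank-1 table: O = E exactly
  expect_equal(suppressWarnings(chi_square_independence(indep))$statistic, 0)
  expect_gt(base$statistic, 0)
  expect_error(chi_square_independence(matrix(c(0, 0, 1, 2), 2)),
               "degenerate")
})

test_that("Monte Carlo chi-square p is seeded and near the asymptotic p", {
  O <- matrix(c(25, 10, 15, 30), 2)
  set.seed(5)
  mc1 <- chi_square_independence(O, mode = "monte_carlo", B = 4000)$p_value
  set.seed(5)
  mc2 <- chi_square_independence(O, mode = "monte_carlo", B = 4000)$p_value
  expect_equal(mc1, mc2)
  asym <- chi_square_independence(O)$p_value
  expect_lt(abs(mc1 - asym), 0.02)
})

test_that("screening routes by feature type and flags a 1-SD shift at n = 200/group", {
  set.seed(21)
  n <- 200
  y <- rep(c("FBTP", "NFBTP"), each = n)
  data <- data.frame(
    shifted = rnorm(2 * n, ifelse(y == "FBTP", 1, 0)),
    flat = rnorm(2 * n),
    code = sample(0:2, 2 * n, replace = TRUE),
    constant = 1)
  ft <- feature_table(
    data, feature_spec(names(data),
                       c("continuous", "continuous", "discrete",
                         "continuous"),
                       nominal = c(FALSE, FALSE, TRUE, FALSE)),
    factor(y, levels = c("FBTP", "NFBTP")))
  scr <- screen_features(ft)
  expect_equal(attr(scr, "skipped"), "constant")
  expect_equal(scr$method[scr$feature == "code"], "chi_square")
  expect_match(scr$method[scr$feature == "shifted"], "mann_whitney")
  expect_lt(scr$p_value[scr$feature == "shifted"], 1e-3)
  expect_true(scr$significant[scr$feature == "shifted"])
  expect_equal(scr$feature[1], "shifted") # sorted by p
})

test_that("screening at alpha = 1 passes everything; BH adjustment is monotone", {
  tab <- make_kind_split_table(n1 = 30, n2 = 30, seed = 2)
  all_pass <- screen_features(tab, alpha = 1)
  expect_true(all(all_pass$significant))
  raw <- screen_features(tab)
  bh <- screen_features(tab, adjust = "BH")
  expect_true(all(bh$p_value >= raw$p_value - 1e-12))
})
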