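# Shared fixture builders. Everything is generated in code at test time.

# A small mixed-kind table with one informative feature per kind.
make_kind_split_table <- function(n1 = 60, n2 = 60, seed = 1,
                                  shift = 1.2) {
  set.seed(seed)
  y <- rep(c("FBTP", "NFBTP"), c(n1, n2))
  n <- n1 + n2
  data <- data.frame(
    xc = rnorm(n, ifelse(y == "FBTP", shift, 0), 1),
    xd = vapply(y, function(c_) {
      p <- if (c_ == "FBTP") c(.6, .3, .1) else c(.2, .3, .5)
      sample(0:2, 1, prob = p)
    }, numeric(1)),
    xb = rbinom(n, 1, ifelse(y == "FBTP", .75, .25)),
    noise = rnorm(n)
  )
  feature_table(
    data,
    feature_spec(names(data),
                 c("continuous", "discrete", "binary", "continuous")),
    factor(y, levels = c("FBTP", "NFBTP")))
}

# Kind-split cohort on which every base learner is well-specified: a shifted
# normal, multinomial counts (total 8 events over three count features with
# class-specific proportions) and a Bernoulli flag. Used together with its
# closed-form Bayes classifier.
make_count_cohort <- function(n1, n2, seed) {
  set.seed(seed)
  y <- rep(c("FBTP", "NFBTP"), c(n1, n2))
  n <- n1 + n2
  pr <- list(FBTP = c(.5, .3, .2), NFBTP = c(.2, .3, .5))
  cnts <- t(vapply(y, function(c_) {
    as.numeric(stats::rmultinom(1, 8, pr[[c_]]))
  }, numeric(3)))
  data <- data.frame(
    xc = rnorm(n, ifelse(y == "FBTP", 1, 0), 1),
    d1 = cnts[, 1], d2 = cnts[, 2], d3 = cnts[, 3],
    xb = rbinom(n, 1, ifelse(y == "FBTP", .7, .3)))
  feature_table(
    data,
    feature_spec(names(data),
                 c("continuous", "discrete", "discrete", "discrete",
                   "binary")),
    factor(y, levels = c("FBTP", "NFBTP")))
}

# True-model plug-in classifier for make_count_cohort (equal priors).
count_cohort_bayes_labels <- function(data) {
  ll1 <- dnorm(data$xc, 1, 1, log = TRUE) +
    data$d1 * log(.5) + data$d2 * log(.3) + data$d3 * log(.2) +
    ifelse(data$xb == 1, log(.7), log(.3))
  ll2 <- dnorm(data$xc, 0, 1, log = TRUE) +
    data$d1 * log(.2) + data$d2 * log(.3) + data$d3 * log(.5) +
    ifelse(data$xb == 1, log(.3), log(.7))
  ifelse(ll1 >= ll2, "FBTP", "NFBTP")
}

# Brute-force exact Mann-Whitney oracle: enumerate every assignment of n1
# pooled values to group 1, compute U per the rank-sum identity, and read the
# two-sided p off the enumerated distribution. Independent of the package's
# dynamic-programming path.
mw_exact_oracle <- function(g1, g2) {
  pooled <- c(g1, g2)
  n1 <- length(g1)
  r <- rank(pooled)
  u_of <- function(idx) {
    n1 * length(g2) + n1 * (n1 + 1) / 2 - sum(r[idx])
  }
  u_obs <- u_of(seq_len(n1))
  all_u <- apply(utils::combn(length(pooled), n1), 2, u_of)
  p_le <- mean(all_u <= u_obs)
  p_ge <- mean(all_u >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Brute-force Borda oracle: materialize every (feature, list, points) triple
# in a long data.frame and aggregate.
borda_oracle <- function(rankings) {
  long <- do.call(rbind, lapply(rankings, function(rl) {
    data.frame(feature = rl$features,
               points = rl$N - seq_len(rl$N) + 1)
  }))
  agg <- aggregate(points ~ feature, data = long, FUN = sum)
  agg <- agg[order(-agg$points, agg$feature), ]
  rownames(agg) <- NULL
  agg
}

# A ranking list whose order is an arbitrary permutation of given features,
# with strictly decreasing scores.
random_ranking <- function(method, features) {
  perm <- sample(features)
  ranking_list(method, setNames(rev(seq_along(perm)), perm))
}
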