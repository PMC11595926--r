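# The three type-partitioned naive-Bayes base learners of the stacking
# ensemble: Gaussian (continuous), multinomial (non-negative integer codes),
# Bernoulli (0/1 flags). Each returns class posteriors.

nb_priors <- function(y) {
  y <- as.factor(y)
  tab <- table(y)
  list(levels = levels(y), log_prior = log(as.numeric(tab) / sum(tab)))
}

#' Gaussian naive Bayes
#'
#' Per class and feature, a normal density with the class-conditional mean
#' and variance. Variances are smoothed by \code{eps} times the largest
#' feature variance (so a within-class constant feature degrades gracefully
#' instead of producing a degenerate density).
#'
#' @param X numeric matrix (continuous features).
#' @param y class labels (factor, both classes present).
#' @param eps variance-smoothing fraction.
#' @return object of class \code{"nb_gaussian"}.
#' @export
nb_gaussian <- function(X, y, eps = 1e-9) {
  X <- as.matrix(X)
  pr <- nb_priors(y)
  yf <- factor(y, levels = pr$levels)
  mu <- do.call(rbind, lapply(pr$levels, function(l)
    colMeans(X[yf == l, , drop = FALSE])))
  v <- do.call(rbind, lapply(pr$levels, function(l)
    apply(X[yf == l, , drop = FALSE], 2, var)))
  v[is.na(v)] <- 0
  smooth <- eps * max(apply(X, 2, var), 1e-12)
  v <- v + smooth
  structure(list(priors = pr, mu = mu, var = v), class = "nb_gaussian")
}

#' @export
predict.nb_gaussian <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  ll <- vapply(seq_along(object$priors$levels), function(c_) {
    object$priors$log_prior[c_] + rowSums(
      -0.5 * log(2 * pi * matrix(object$var[c_, ], nrow(X), ncol(X),
                                 byrow = TRUE)) -
        sweep(X, 2, object$mu[c_, ])^2 /
          (2 * matrix(object$var[c_, ], nrow(X), ncol(X), byrow = TRUE)))
  }, numeric(nrow(X)))
  ll <- matrix(ll, nrow = nrow(X))
  posterior_from_loglik(ll, object$priors$levels)
}

#' Multinomial naive Bayes
#'
#' Count-style likelihood over non-negative integer features with Laplace
#' smoothing \code{alpha}: within class c, feature j has event probability
#' proportional to its summed counts. Negative codes (e.g. the -1
#' missing-data code) must be shifted non-negative by the caller.
#'
#' @param X matrix of non-negative integers.
#' @param y class labels.
#' @param alpha Laplace smoothing.
#' @return object of class \code{"nb_multinomial"}.
#' @export
nb_multinomial <- function(X, y, alpha = 1) {
  X <- as.matrix(X)
  if (any(X < 0) || any(X != round(X))) {
    stop("multinomial NB requires non-negative integer features ",
         "(shift-encode negative codes first)", call. = FALSE)
  }
  pr <- nb_priors(y)
  yf <- factor(y, levels = pr$levels)
  log_theta <- do.call(rbind, lapply(pr$levels, function(l) {
    cnt <- colSums(X[yf == l, , drop = FALSE]) + alpha
    log(cnt / sum(cnt))
  }))
  structure(list(priors = pr, log_theta = log_theta),
            class = "nb_multinomial")
}

#' @export
predict.nb_multinomial <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  ll <- X %*% t(object$log_theta)
  ll <- sweep(ll, 2, object$priors$log_prior, "+")
  posterior_from_loglik(ll, object$priors$levels)
}

#' Bernoulli naive Bayes
#'
#' Independent Bernoulli likelihood per binary feature with Laplace-smoothed
#' class-conditional success probabilities.
#'
#' @param X matrix of 0/1 features.
#' @param y class labels.
#' @param alpha Laplace smoothing.
#' @return object of class \code{"nb_bernoulli"}.
#' @export
nb_bernoulli <- function(X, y, alpha = 1) {
  X <- as.matrix(X)
  if (!all(X %in% c(0, 1))) {
    stop("Bernoulli NB requires 0/1 features", call. = FALSE)
  }
  pr <- nb_priors(y)
  yf <- factor(y, levels = pr$levels)
  theta <- do.call(rbind, lapply(pr$levels, function(l) {
    xs <- X[yf == l, , drop = FALSE]
    (colSums(xs) + alpha) / (nrow(xs) + 2 * alpha)
  }))
  structure(list(priors = pr, theta = theta), class = "nb_bernoulli")
}

#' @export
predict.nb_bernoulli <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  ll <- vapply(seq_along(object$priors$levels), function(c_) {
    th <- matrix(object$theta[c_, ], nrow(X), ncol(X), byrow = TRUE)
    object$priors$log_prior[c_] +
      rowSums(X * log(th) + (1 - X) * log(1 - th))
  }, numeric(nrow(X)))
  posterior_from_loglik(matrix(ll, nrow = nrow(X)), object$priors$levels)
}

# log-likelihood matrix (rows = samples, cols = classes) -> posteriors
posterior_from_loglik <- function(ll, levels) {
  m <- apply(ll, 1, max)
  p <- exp(ll - m)
  p <- p / rowSums(p)
  colnames(p) <- levels
  p
}
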