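# The feature-importance battery feeding the Borda consensus: three
# correlation scores aggregated into one list, information gain, MRMR,
# two RFE wrappers, LDA loadings and LASSO coefficients.

#' Construct a ranking list
#'
#' One method's ordered feature list: rank 1 is most important. Scores are
#' sorted non-increasing; ties broken alphabetically by feature name so every
#' score-to-rank conversion is deterministic and stable across reruns.
#'
#' @param method method tag.
#' @param scores named numeric vector of raw importances (higher = better).
#' @return list of class \code{"ranking_list"}: \code{method},
#'   \code{features} (ordered), \code{scores} (in that order), \code{N}.
#' @export
ranking_list <- function(method, scores) {
  if (is.null(names(scores)) || anyDuplicated(names(scores))) {
    stop("scores must be uniquely named", call. = FALSE)
  }
  ord <- order(-scores, names(scores))
  structure(list(method = method, features = names(scores)[ord],
                 scores = unname(scores[ord]), N = length(scores)),
            class = "ranking_list")
}

#' @export
print.ranking_list <- function(x, ...) {
  cat("ranking_list [", x$method, "] N =", x$N, "; top:",
      paste(head(x$features, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Spearman rank-correlation importance
#'
#' \eqn{\rho = 1 - 6 \sum d_i^2 / (n(n^2-1))} computed on midranks, where
#' \eqn{d_i} is the rank difference of observation i between the feature and
#' the 0/1 label. Importance downstream is \eqn{|\rho|}.
#'
#' @param x numeric feature values (n >= 3).
#' @param y binary labels coercible to 0/1.
#' @return rho (signed).
#' @export
spearman_score <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (length(unique(x)) < 2) {
    warning("constant feature: spearman score 0", call. = FALSE)
    return(0)
  }
  d <- rank(x) - rank(as.numeric(y))
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

#' Point-biserial correlation importance
#'
#' \eqn{r_{pb} = \frac{M_1 - M_2}{\sigma}\sqrt{\frac{n_1 n_2}{n(n-1)}}} with
#' \eqn{\sigma} the population SD of the pooled sample. The \eqn{n(n-1)}
#' denominator is implemented as printed in the source formulation; the
#' textbook variant with \eqn{n^2} (which bounds \eqn{|r_{pb}|} by 1) is
#' selectable via \code{form}.
#'
#' @param x numeric feature values.
#' @param y binary labels; group 1 = first factor level (or y == unique low).
#' @param form \code{"printed"} (default) or \code{"textbook"}.
#' @return r_pb (signed).
#' @export
point_biserial_score <- function(x, y, form = c("printed", "textbook")) {
  form <- match.arg(form)
  y <- as.factor(y)
  stopifnot(nlevels(y) == 2)
  g1 <- y == levels(y)[1]
  n <- length(x)
  n1 <- sum(g1)
  n2 <- n - n1
  if (n1 == 0 || n2 == 0) stop("both classes must be present", call. = FALSE)
  sigma <- sqrt(mean((x - mean(x))^2))
  if (sigma == 0) {
    warning("zero-variance feature: point-biserial score 0", call. = FALSE)
    return(0)
  }
  denom <- if (form == "printed") n * (n - 1) else n^2
  (mean(x[g1]) - mean(x[!g1])) / sigma * sqrt(n1 * n2 / denom)
}

# Logistic coefficients, robust to p >= n and to perfect separation: plain
# glm when well-posed, ridge (glmnet, alpha = 0) otherwise.
robust_logistic_coefs <- function(X, y, ridge_lambda = 1e-2) {
  X <- as.matrix(X)
  y01 <- as.integer(as.factor(y)) - 1L
  p <- ncol(X)
  n <- nrow(X)
  use_ridge <- p + 1 >= n
  beta <- NULL
  if (!use_ridge) {
    fit <- withCallingHandlers(
      glm(y01 ~ X, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                  conditionMessage(w))) {
          use_ridge <<- TRUE
        }
        invokeRestart("muffleWarning")
      })
    if (!use_ridge) beta <- coef(fit)[-1]
  }
  if (use_ridge) {
    fit <- glmnet::glmnet(X, y01, family = "binomial", alpha = 0,
                          lambda = ridge_lambda, standardize = FALSE)
    beta <- as.numeric(coef(fit))[-1]
  }
  names(beta) <- colnames(X)
  beta[is.na(beta)] <- 0
  beta
}

#' Multivariable logistic-regression importance (BCRAC)
#'
#' Fits one logistic model of the label on all supplied (standardized)
#' features; the importance of feature i is the absolute value of its
#' coefficient. With more features than samples, or under perfect separation,
#' a ridge-penalized fit is substituted (and noted via message).
#'
#' @param X numeric matrix of standardized features (named columns).
#' @param y binary labels.
#' @param ridge_lambda ridge penalty used by the fallback.
#' @return named vector of \eqn{|\beta_i|}.
#' @export
bcrac_score <- function(X, y, ridge_lambda = 1e-2) {
  abs(robust_logistic_coefs(X, y, ridge_lambda))
}

# Quartile binning on the vector's own quantiles; collapses duplicate breaks.
discretize_quartiles <- function(x, breaks = NULL) {
  if (is.null(breaks)) {
    breaks <- unique(quantile(x, probs = c(0, .25, .5, .75, 1), na.rm = TRUE))
  }
  if (length(breaks) < 2) return(factor(rep("b1", length(x))))
  cut(x, breaks = breaks, include.lowest = TRUE)
}

entropy_bits <- function(x) {
  p <- table(x)
  p <- p[p > 0] / sum(p)
  -sum(p * log2(p))
}

mutual_information_bits <- function(a, b) {
  joint <- table(a, b)
  n <- sum(joint)
  pj <- joint / n
  pa <- rowSums(pj)
  pb <- colSums(pj)
  keep <- pj > 0
  sum(pj[keep] * log2(pj[keep] / outer(pa, pb)[keep]))
}

#' Information-gain importance
#'
#' \eqn{IG(T, a) = H(T) - H(T|a)} in bits; continuous features are quartile
#' binned first. Always in \eqn{[0, H(T)]}.
#'
#' @param x feature values (categorical, or numeric to be binned).
#' @param y binary labels.
#' @param discretize bin numeric x at its quartiles (default TRUE).
#' @return information gain in bits.
#' @export
information_gain_score <- function(x, y, discretize = TRUE) {
  a <- if (discretize && is.numeric(x) && length(unique(x)) > 8) {
    discretize_quartiles(x)
  } else {
    factor(x)
  }
  mutual_information_bits(a, factor(y))
}

#' Minimum-redundancy maximum-relevance feature order
#'
#' Greedy forward selection: the first pick maximizes mutual information with
#' the label; each subsequent pick maximizes relevance minus the mean mutual
#' information with the already selected set. Continuous features are
#' quartile binned. Ties break alphabetically.
#'
#' @param X data.frame/matrix of features.
#' @param y binary labels.
#' @param k number of features to order (default: all).
#' @return character vector: the selection order (rank 1 first).
#' @export
mrmr_rank <- function(X, y, k = ncol(X)) {
  X <- as.data.frame(X)
  if (k > ncol(X)) {
    warning("k exceeds the number of features; truncated", call. = FALSE)
    k <- ncol(X)
  }
  disc <- lapply(X, function(col) {
    if (is.numeric(col) && length(unique(col)) > 8) {
      discretize_quartiles(col)
    } else {
      factor(col)
    }
  })
  feats <- names(X)
  rel <- vapply(disc, mutual_information_bits, numeric(1), b = factor(y))
  selected <- character(0)
  remaining <- feats
  while (length(selected) < k) {
    crit <- vapply(remaining, function(f) {
      red <- if (length(selected) == 0) 0 else {
        mean(vapply(selected, function(s) {
          mutual_information_bits(disc[[f]], disc[[s]])
        }, numeric(1)))
      }
      rel[[f]] - red
    }, numeric(1))
    best <- remaining[order(-crit, remaining)][1]
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  selected
}

#' Recursive feature elimination ranking
#'
#' Repeatedly fits the model on the surviving features and removes the least
#' important one (smallest \eqn{|\beta|} for the logistic wrapper; smallest
#' mean decrease in Gini impurity for the random-forest wrapper) until one
#' remains. The reversed elimination order is the ranking. Among tied minima
#' the alphabetically last feature is eliminated first, keeping reruns
#' identical.
#'
#' @param X numeric matrix of features (standardized for the logistic model).
#' @param y binary labels.
#' @param model_kind \code{"logistic"} or \code{"random_forest"}.
#' @param seed integer seed (drives the forests).
#' @param ntree trees per forest fit.
#' @return character vector of features, rank 1 first.
#' @export
wrapper_rfe_rank <- function(X, y, model_kind = c("logistic", "random_forest"),
                             seed = 1L, ntree = 250) {
  model_kind <- match.arg(model_kind)
  X <- as.matrix(X)
  yf <- as.factor(y)
  surviving <- colnames(X)
  eliminated <- character(0)
  step <- 0L
  while (length(surviving) > 1) {
    step <- step + 1L
    imp <- if (model_kind == "logistic") {
      abs(robust_logistic_coefs(X[, surviving, drop = FALSE], yf))
    } else {
      set.seed(seed + step)
      rf <- randomForest::randomForest(X[, surviving, drop = FALSE], yf,
                                       ntree = ntree)
      imp_ <- rf$importance[, "MeanDecreaseGini"]
      names(imp_) <- surviving
      imp_
    }
    # eliminate the weakest; among ties the alphabetically last goes first
    drop_ <- sort(surviving[imp == min(imp)], decreasing = TRUE)[1]
    eliminated <- c(drop_, eliminated)
    surviving <- setdiff(surviving, drop_)
  }
  c(surviving, eliminated)
}

#' Linear-discriminant importance
#'
#' Maximizes the between- to within-class scatter ratio
#' \eqn{J(W) = W^T S_b W / W^T S_w W}; for two classes the optimal direction
#' is \eqn{S_w^{-1}(\mu_1 - \mu_2)}. Importance is the absolute loading of
#' each (standardized) feature on that direction. A singular within-class
#' scatter triggers diagonal shrinkage.
#'
#' @param X numeric matrix of standardized features.
#' @param y binary labels.
#' @param shrink shrinkage fraction applied when \eqn{S_w} is ill-conditioned.
#' @return named vector of absolute loadings.
#' @export
lda_score <- function(X, y, shrink = 1e-3) {
  X <- as.matrix(X)
  yf <- as.factor(y)
  stopifnot(nlevels(yf) == 2)
  idx1 <- yf == levels(yf)[1]
  mu1 <- colMeans(X[idx1, , drop = FALSE])
  mu2 <- colMeans(X[!idx1, , drop = FALSE])
  center <- function(M) sweep(M, 2, colMeans(M))
  S1 <- crossprod(center(X[idx1, , drop = FALSE]))
  S2 <- crossprod(center(X[!idx1, , drop = FALSE]))
  Sw <- S1 + S2
  w <- tryCatch({
    if (rcond(Sw) < 1e-10) stop("ill-conditioned")
    solve(Sw, mu1 - mu2)
  }, error = function(e) {
    message("lda_score: singular within-class scatter; shrinkage applied")
    solve(Sw + shrink * mean(diag(Sw)) * diag(ncol(X)), mu1 - mu2)
  })
  out <- abs(w)
  names(out) <- colnames(X)
  out
}

#' L1-penalized (LASSO) importance
#'
#' Logistic loss with an L1 penalty by default (the coherent choice for a
#' binary outcome; squared-error loss is selectable). The penalty is chosen
#' by internal cross-validation with a deterministic fold assignment unless
#' \code{lambda} is fixed. Importance is \eqn{|\beta_j|}; zeroed features
#' rank last.
#'
#' @param X numeric matrix of standardized features.
#' @param y binary labels.
#' @param lambda fixed penalty, or NULL for CV choice.
#' @param family \code{"binomial"} (default) or \code{"gaussian"}.
#' @param nfolds CV folds for the penalty path.
#' @return named vector of \eqn{|\beta_j|} at the chosen penalty.
#' @export
lasso_score <- function(X, y, lambda = NULL, family = c("binomial", "gaussian"),
                        nfolds = 5) {
  family <- match.arg(family)
  X <- as.matrix(X)
  yy <- if (family == "binomial") as.integer(as.factor(y)) - 1L else
    as.numeric(y)
  if (is.null(lambda)) {
    foldid <- rep_len(seq_len(nfolds), nrow(X)) # deterministic assignment
    cv <- glmnet::cv.glmnet(X, yy, family = family, alpha = 1,
                            foldid = foldid, standardize = FALSE)
    lambda <- cv$lambda.min
  }
  fit <- glmnet::glmnet(X, yy, family = family, alpha = 1, lambda = lambda,
                        standardize = FALSE)
  beta <- abs(as.numeric(coef(fit))[-1])
  names(beta) <- colnames(X)
  if (all(beta == 0)) {
    warning("all coefficients shrunk to zero at this penalty", call. = FALSE)
  }
  beta
}

# ---------------------------------------------------------------------------

# Keep each ranking's top `max_continuous` continuous features plus all
# categorical ones, preserving order; N becomes the kept-list length.
truncate_ranking <- function(rl, specs, max_continuous = 50) {
  cont <- specs$name[specs$kind == "continuous"]
  is_cont <- rl$features %in% cont
  keep <- !is_cont | cumsum(is_cont) <= max_continuous
  structure(list(method = rl$method, features = rl$features[keep],
                 scores = rl$scores[keep], N = sum(keep)),
            class = "ranking_list")
}

#' Build the consensus input: one ranking list per method
#'
#' Runs the method battery on an encoded table: the aggregated correlation
#' ranking (Spearman, point-biserial and multivariable-logistic importances
#' combined by mean rank), information gain, MRMR, RFE with a logistic model,
#' RFE with random forests, LDA loadings, and LASSO -- seven lists in total.
#' Continuous features beyond the top 50 of a list are dropped before
#' consensus; categorical features are never truncated. A method failing on
#' degenerate data is omitted with a warning and the consensus proceeds on
#' the rest.
#'
#' @param table a \code{\link{feature_table}} (cleaned, numerically encoded).
#' @param labels factor FBTP/NFBTP; default \code{table$labels}.
#' @param seed integer; drives the random-forest wrapper.
#' @param max_continuous per-list cap on continuous features (default 50).
#' @param ntree trees per forest in the RF wrapper.
#' @return named list of \code{\link{ranking_list}} objects.
#' @export
build_ranking_lists <- function(table, labels = table$labels, seed = 1L,
                                max_continuous = 50, ntree = 250) {
  stopifnot(inherits(table, "feature_table"), !is.null(labels))
  labels <- factor(labels, levels = c("FBTP", "NFBTP"))
  X <- as.matrix(table$data)
  # impute (full-table medians; consensus is computed once per evaluation
  # context) and standardize continuous columns so coefficients compare
  for (j in seq_len(ncol(X))) {
    if (anyNA(X[, j])) X[, j] <- impute_missing(X[, j])
  }
  cont <- table$specs$kind == "continuous"
  if (any(cont)) {
    keep <- apply(X[, cont, drop = FALSE], 2, function(c) sd(c) > 0)
    zf <- zscore_fit_transform(X[, cont, drop = FALSE][, keep, drop = FALSE])
    X[, colnames(zf$transformed)] <- zf$transformed
  }
  y <- labels
  feats <- colnames(X)

  run <- function(method, fun) {
    tryCatch(fun(), error = function(e) {
      warning("ranking method ", sQuote(method), " failed (",
              conditionMessage(e), "); omitted from consensus",
              call. = FALSE)
      NULL
    })
  }

  lists <- list()
  lists$correlation <- run("correlation", function() {
    sp <- vapply(feats, function(f)
      abs(suppressWarnings(spearman_score(X[, f], as.integer(y) - 1))),
      numeric(1))
    pb <- vapply(feats, function(f)
      abs(suppressWarnings(point_biserial_score(X[, f], y))), numeric(1))
    bc <- bcrac_score(X, y)
    to_rank <- function(s) {
      r <- match(names(s), names(s)[order(-s, names(s))])
      names(r) <- names(s)
      r
    }
    mean_rank <- (to_rank(sp) + to_rank(pb) + to_rank(bc[feats])) / 3
    ranking_list("correlation", setNames(length(feats) - mean_rank, feats))
  })
  lists$information_gain <- run("information_gain", function() {
    ig <- vapply(feats, function(f)
      information_gain_score(X[, f], y), numeric(1))
    ranking_list("information_gain", ig)
  })
  lists$mrmr <- run("mrmr", function() {
    ord <- mrmr_rank(as.data.frame(X), y)
    ranking_list("mrmr", setNames(rev(seq_along(ord)), ord))
  })
  lists$rfe_logistic <- run("rfe_logistic", function() {
    ord <- wrapper_rfe_rank(X, y, "logistic", seed = seed)
    ranking_list("rfe_logistic", setNames(rev(seq_along(ord)), ord))
  })
  lists$rfe_random_forest <- run("rfe_random_forest", function() {
    ord <- wrapper_rfe_rank(X, y, "random_forest", seed = seed, ntree = ntree)
    ranking_list("rfe_random_forest", setNames(rev(seq_along(ord)), ord))
  })
  lists$lda <- run("lda", function() {
    ranking_list("lda", lda_score(X, y))
  })
  lists$lasso <- run("lasso", function() {
    ranking_list("lasso", lasso_score(X, y))
  })
  lists <- Filter(Negate(is.null), lists)
  lapply(lists, truncate_ranking, specs = table$specs,
         max_continuous = max_continuous)
}
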