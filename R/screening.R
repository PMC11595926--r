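# Univariate screening: Mann-Whitney U for continuous/ordinal features,
# chi-square independence for nominal ones, FBTP vs NFBTP.

# Number of size-k subsets of ranks 1..N by rank sum, as a matrix of counts
# indexed [k + 1, sum + 1]. Dynamic programming over the Gaussian binomial
# recurrence; exact integer counts held in doubles (safe well beyond the
# cohort sizes used here).
rank_sum_counts <- function(n1, N) {
  smax <- sum((N - n1 + 1):N)
  cnt <- matrix(0, nrow = n1 + 1, ncol = smax + 1)
  cnt[1, 1] <- 1
  for (i in seq_len(N)) {
    kmax <- min(i, n1)
    for (k in kmax:1) {
      reach <- sum((i - k + 1):i) # max sum using ranks <= i
      s <- i:min(reach, smax)
      cnt[k + 1, s + 1] <- cnt[k + 1, s + 1] + cnt[k, s - i + 1]
    }
  }
  cnt
}

#' Mann-Whitney U test of two independent groups
#'
#' The statistic is \eqn{U = n_1 n_2 + n_1(n_1+1)/2 - R_1} with \eqn{R_1} the
#' midrank sum of the first group (by screening convention, the NFBTP class).
#' Exact mode derives the two-sided p from the full null distribution of the
#' rank sum over all \eqn{\binom{n_1+n_2}{n_1}} assignments (tie-free data
#' only; with ties it refuses and instructs a fallback). Normal mode uses the
#' tie-corrected normal approximation with continuity correction. Auto picks
#' exact when \eqn{n_1+n_2 \le 16} and tie-free, else normal.
#'
#' @param group1,group2 numeric vectors (non-empty).
#' @param mode \code{"exact"}, \code{"normal"} or \code{"auto"}.
#' @param correct continuity correction in normal mode (default TRUE).
#' @return list of class \code{"rlt_test"}: \code{statistic} (U), \code{p_value}
#'   (two-sided), \code{method}, \code{n1}, \code{n2}, \code{R1}.
#' @examples
#' mann_whitney_u(c(4, 5, 6), c(1, 2, 3), mode = "exact") # U = 0, p = 0.1
#' @export
mann_whitney_u <- function(group1, group2, mode = c("auto", "exact", "normal"),
                           correct = TRUE) {
  mode <- match.arg(mode)
  group1 <- group1[!is.na(group1)]
  group2 <- group2[!is.na(group2)]
  n1 <- length(group1)
  n2 <- length(group2)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(group1, group2)
  r <- rank(pooled) # midranks
  R1 <- sum(r[seq_len(n1)])
  U <- n1 * n2 + n1 * (n1 + 1) / 2 - R1
  ties <- any(duplicated(pooled))
  if (mode == "auto") {
    mode <- if (n1 + n2 <= 16 && !ties) "exact" else "normal"
  }
  N <- n1 + n2
  if (mode == "exact") {
    if (ties) {
      stop("exact Mann-Whitney p is only defined for tie-free data; ",
           "use mode = \"normal\"", call. = FALSE)
    }
    cnt <- rank_sum_counts(n1, N)[n1 + 1, ]
    total <- choose(N, n1)
    # U is a monotone (decreasing) function of R1; enumerate over R1.
    r1_grid <- seq_len(length(cnt)) - 1
    u_grid <- n1 * n2 + n1 * (n1 + 1) / 2 - r1_grid
    p_le <- sum(cnt[u_grid <= U]) / total
    p_ge <- sum(cnt[u_grid >= U]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "mann_whitney_exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      cc <- if (correct) sign(U - mu) * 0.5 else 0
      z <- (U - mu - cc) / sigma
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "mann_whitney_normal"
  }
  structure(list(statistic = U, p_value = p, method = method,
                 n1 = n1, n2 = n2, R1 = R1),
            class = "rlt_test")
}

#' Chi-square test of independence on a contingency table
#'
#' Expected counts come from the product of the margins over the total; the
#' statistic is \eqn{\chi^2 = \sum (O_i - E_i)^2 / E_i} without continuity
#' correction. Asymptotic p uses \eqn{(r-1)(c-1)} degrees of freedom; Monte
#' Carlo mode resamples tables with both margins fixed.
#'
#' @param table r x c matrix of non-negative counts (r, c >= 2 after dropping
#'   all-zero margins is required).
#' @param mode \code{"asymptotic"} or \code{"monte_carlo"}.
#' @param B Monte Carlo replicates.
#' @return list of class \code{"rlt_test"}: \code{statistic}, \code{p_value},
#'   \code{df}, \code{observed}, \code{expected}, \code{method},
#'   \code{small_expected} (TRUE when any expected count < 5).
#' @export
chi_square_independence <- function(table,
                                    mode = c("asymptotic", "monte_carlo"),
                                    B = 2000) {
  mode <- match.arg(mode)
  O <- as.matrix(table)
  if (any(O < 0)) stop("counts must be non-negative", call. = FALSE)
  rs <- rowSums(O)
  cs <- colSums(O)
  if (any(rs == 0) || any(cs == 0)) {
    stop("degenerate table: all-zero row or column margin", call. = FALSE)
  }
  if (nrow(O) < 2 || ncol(O) < 2) {
    stop("need at least a 2 x 2 table", call. = FALSE)
  }
  n <- sum(O)
  E <- outer(rs, cs) / n
  stat <- sum((O - E)^2 / E)
  df <- (nrow(O) - 1) * (ncol(O) - 1)
  small <- any(E < 5)
  if (small) {
    warning("expected count below 5; asymptotic p may be inaccurate",
            call. = FALSE)
  }
  if (mode == "asymptotic") {
    p <- pchisq(stat, df = df, lower.tail = FALSE)
    method <- "chi_square"
  } else {
    sims <- stats::r2dtable(B, rs, cs)
    stats_sim <- vapply(sims, function(t) sum((t - E)^2 / E), numeric(1))
    p <- (1 + sum(stats_sim >= stat - 1e-12)) / (B + 1)
    method <- "chi_square_mc"
  }
  structure(list(statistic = stat, p_value = p, df = df, observed = O,
                 expected = E, method = method, small_expected = small),
            class = "rlt_test")
}

#' @export
print.rlt_test <- function(x, ...) {
  cat(x$method, ": statistic =", signif(x$statistic, 5),
      ", p =", signif(x$p_value, 4), "\n")
  invisible(x)
}

#' Screen every feature against the response label
#'
#' Continuous and ordered discrete features are compared between classes with
#' the Mann-Whitney U test (first group = NFBTP); nominal and binary features
#' with the chi-square independence test against the label. Raw p-values are
#' reported by default, matching the source table's presentation;
#' Benjamini-Hochberg adjustment is available behind \code{adjust}.
#'
#' @param table a \code{\link{feature_table}}.
#' @param labels factor FBTP/NFBTP; default \code{table$labels}.
#' @param alpha significance threshold for the flag column.
#' @param adjust \code{"none"} (default) or any \code{\link[stats]{p.adjust}}
#'   method.
#' @param mw_mode passed to \code{\link{mann_whitney_u}}.
#' @param first_group which class is "group 1" in the U statistic.
#' @return data.frame sorted by p: feature, kind, method, statistic, df,
#'   p_value, significant. Features with fewer than two distinct observed
#'   values are skipped; their names are in \code{attr(, "skipped")}.
#' @export
screen_features <- function(table, labels = table$labels, alpha = 0.05,
                            adjust = "none", mw_mode = "auto",
                            first_group = "NFBTP") {
  stopifnot(inherits(table, "feature_table"), !is.null(labels))
  labels <- factor(labels, levels = c("FBTP", "NFBTP"))
  g1 <- labels == first_group
  rows <- list()
  skipped <- character(0)
  for (j in seq_len(ncol(table$data))) {
    nm <- table$specs$name[j]
    x <- table$data[[j]]
    obs <- x[!is.na(x)]
    if (length(unique(obs)) < 2) {
      skipped <- c(skipped, nm)
      next
    }
    nominal <- table$specs$nominal[j] || table$specs$kind[j] == "binary"
    res <- if (nominal) {
      tab <- base::table(factor(x), labels)
      tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
      if (nrow(tab) < 2 || ncol(tab) < 2) {
        skipped <- c(skipped, nm)
        next
      }
      suppressWarnings(chi_square_independence(tab))
    } else {
      mann_whitney_u(x[g1 & !is.na(x)], x[!g1 & !is.na(x)], mode = mw_mode)
    }
    rows[[length(rows) + 1]] <- data.frame(
      feature = nm, kind = table$specs$kind[j], method = res$method,
      statistic = res$statistic,
      df = if (is.null(res$df)) NA_real_ else res$df,
      p_value = res$p_value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(feature = character(0), kind = character(0),
                      method = character(0), statistic = numeric(0),
                      df = numeric(0), p_value = numeric(0),
                      significant = logical(0))
    attr(out, "skipped") <- skipped
    return(out)
  }
  if (adjust != "none") out$p_value <- stats::p.adjust(out$p_value, adjust)
  out$significant <- out$p_value < alpha
  out <- out[order(out$p_value, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
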