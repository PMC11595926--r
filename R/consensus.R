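# Borda-count fusion of the base rankings into one consensus score.

#' Borda-count consensus over ranking lists
#'
#' For each list of length N, the feature at rank r receives N - r + 1
#' points; points are summed across lists. A feature absent from a list
#' contributes nothing from it. The output is sorted by total score
#' descending, ties broken alphabetically (the accumulation itself sorts by
#' value only).
#'
#' @param rankings non-empty list of \code{\link{ranking_list}} objects, each
#'   internally duplicate-free.
#' @return data.frame of class \code{"consensus_ranking"}: \code{feature},
#'   \code{score}, \code{n_methods} (lists containing the feature);
#'   per-method points in \code{attr(, "per_method")}.
#' @examples
#' a <- ranking_list("m1", c(f1 = 3, f2 = 2, f3 = 1))
#' b <- ranking_list("m2", c(f1 = 9, f3 = 5, f2 = 4))
#' borda_consensus(list(a, b)) # f1: 6, f2/f3: 3 each (f2 first, alphabetical)
#' @export
borda_consensus <- function(rankings) {
  if (length(rankings) == 0) stop("no ranking lists supplied", call. = FALSE)
  for (i in seq_along(rankings)) {
    rl <- rankings[[i]]
    if (!inherits(rl, "ranking_list")) {
      stop("element ", i, " is not a ranking_list", call. = FALSE)
    }
    if (anyDuplicated(rl$features)) {
      stop("duplicate feature in list ", sQuote(rl$method), call. = FALSE)
    }
  }
  scores <- new.env(parent = emptyenv())
  per_method <- list()
  for (rl in rankings) {
    pts <- rl$N - seq_len(rl$N) + 1
    names(pts) <- rl$features
    per_method[[rl$method]] <- pts
    for (f in rl$features) {
      prev <- if (is.null(scores[[f]])) 0 else scores[[f]]
      scores[[f]] <- prev + pts[[f]]
    }
  }
  feats <- ls(scores)
  total <- vapply(feats, function(f) scores[[f]], numeric(1))
  nm <- vapply(feats, function(f) {
    sum(vapply(per_method, function(p) f %in% names(p), logical(1)))
  }, numeric(1))
  ord <- order(-total, feats)
  out <- data.frame(feature = feats[ord], score = unname(total[ord]),
                    n_methods = unname(nm[ord]), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("consensus_ranking", "data.frame")
  attr(out, "per_method") <- per_method
  out
}

#' Select the top features per kind from a consensus
#'
#' Takes the \code{n_continuous} highest-scoring continuous features and the
#' \code{n_categorical} highest-scoring categorical (discrete or binary)
#' features, by consensus order. Defaults reproduce the 30 + 20 split used
#' for the downstream model search. A shortfall returns what exists, with a
#' warning.
#'
#' @param consensus a \code{\link{borda_consensus}} result.
#' @param specs \code{\link{feature_spec}} giving each feature's kind.
#' @param n_continuous,n_categorical selection sizes (defaults 30 and 20).
#' @return character vector of selected features, consensus order preserved
#'   within each kind (continuous first).
#' @export
select_features <- function(consensus, specs, n_continuous = 30,
                            n_categorical = 20) {
  kind <- specs$kind[match(consensus$feature, specs$name)]
  cont <- consensus$feature[!is.na(kind) & kind == "continuous"]
  cate <- consensus$feature[!is.na(kind) & kind != "continuous"]
  if (length(cont) < n_continuous) {
    warning("only ", length(cont), " continuous features available (",
            n_continuous, " requested)", call. = FALSE)
  }
  if (length(cate) < n_categorical) {
    warning("only ", length(cate), " categorical features available (",
            n_categorical, " requested)", call. = FALSE)
  }
  c(head(cont, n_continuous), head(cate, n_categorical))
}
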