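# The type-partitioned naive-Bayes stacking classifier, the baseline model
# battery, LOOCV / k-fold evaluation and the confusion-matrix metrics.

#' Specify a stacked model
#'
#' Selected features are routed by kind to their base learner (continuous ->
#' Gaussian NB, discrete -> multinomial NB, binary -> Bernoulli NB); a base
#' learner with no features is omitted and the meta-learner input shrinks
#' accordingly. The meta-learner consumes the base learners' FBTP posterior
#' probabilities by default (hard labels optionally) and is a sigmoid-kernel
#' support-vector classifier by default, with a logistic alternative.
#'
#' @param features character vector of selected feature names.
#' @param meta \code{"svm_sigmoid"} (default) or \code{"logistic"}.
#' @param meta_input \code{"probabilities"} (default) or \code{"labels"}.
#' @param inner_folds folds for cross-fitting the meta-learner's training
#'   inputs inside the training set (so it never sees resubstitution
#'   predictions).
#' @param seed integer seed fanned out to inner folds.
#' @return list of class \code{"stacked_model_spec"}.
#' @export
stacked_model_spec <- function(features, meta = c("svm_sigmoid", "logistic"),
                               meta_input = c("probabilities", "labels"),
                               inner_folds = 5, seed = 1L) {
  structure(list(features = unique(as.character(features)),
                 meta = match.arg(meta),
                 meta_input = match.arg(meta_input),
                 inner_folds = inner_folds, seed = as.integer(seed)),
            class = "stacked_model_spec")
}

#' Confusion counts from truth and prediction
#'
#' @param truth,pred factors over FBTP/NFBTP (or coercible).
#' @param positive the positive class for precision/recall (FBTP).
#' @return named numeric vector TP, TN, FP, FN.
#' @export
confusion_counts <- function(truth, pred, positive = "FBTP") {
  truth <- as.character(truth)
  pred <- as.character(pred)
  c(TP = sum(truth == positive & pred == positive),
    TN = sum(truth != positive & pred != positive),
    FP = sum(truth != positive & pred == positive),
    FN = sum(truth == positive & pred != positive))
}

#' Classification metrics from confusion counts
#'
#' Accuracy (TP+TN)/(TP+TN+FP+FN), precision TP/(TP+FP), recall TP/(TP+FN),
#' F1 = 2PR/(P+R). A zero denominator yields 0 for the affected metric.
#'
#' @param counts named vector/list with TP, TN, FP, FN (non-negative, not
#'   all zero).
#' @return list: accuracy, precision, recall, f1.
#' @export
compute_metrics <- function(counts) {
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  tot <- tp + tn + fp + fn
  if (tot == 0) stop("no evaluated samples", call. = FALSE)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  list(accuracy = (tp + tn) / tot, precision = prec, recall = rec, f1 = f1)
}

# Deterministic stratified fold assignment: within each class, a seeded
# shuffle then round-robin.
stratified_folds <- function(y, k, seed) {
  y <- as.factor(y)
  fold <- integer(length(y))
  set.seed(seed)
  for (l in levels(y)) {
    idx <- which(y == l)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Per-kind preprocessing fitted on training rows only: median imputation and
# standardization for continuous features; -1-code imputation and a
# non-negative shift for discrete codes; mode imputation for binary flags.
fit_preprocessor <- function(data, specs, train_rows) {
  prep <- list(cols = specs$name, kind = specs$kind)
  prep$median <- prep$center <- prep$scale <- prep$shift <- prep$mode <-
    setNames(rep(NA_real_, length(prep$cols)), prep$cols)
  for (j in seq_along(prep$cols)) {
    x <- data[[prep$cols[j]]][train_rows]
    if (prep$kind[j] == "continuous") {
      prep$median[j] <- median(x, na.rm = TRUE)
      x[is.na(x)] <- prep$median[j]
      prep$center[j] <- mean(x)
      s <- sqrt(mean((x - mean(x))^2))
      prep$scale[j] <- if (is.na(s) || s == 0) 1 else s
    } else if (prep$kind[j] == "discrete") {
      prep$shift[j] <- min(c(x, -1), na.rm = TRUE) # -1 = missing code
    } else {
      tab <- table(x)
      prep$mode[j] <- if (length(tab) == 0) 0 else
        as.numeric(names(tab)[which.max(tab)])
    }
  }
  prep
}

apply_preprocessor <- function(prep, data, rows) {
  out <- matrix(NA_real_, length(rows), length(prep$cols),
                dimnames = list(NULL, prep$cols))
  for (j in seq_along(prep$cols)) {
    x <- data[[prep$cols[j]]][rows]
    if (prep$kind[j] == "continuous") {
      x[is.na(x)] <- prep$median[j]
      x <- (x - prep$center[j]) / prep$scale[j]
    } else if (prep$kind[j] == "discrete") {
      x[is.na(x)] <- -1
      x <- pmax(x - prep$shift[j], 0)
    } else {
      x[is.na(x)] <- prep$mode[j]
    }
    out[, j] <- x
  }
  out
}

base_learner_fits <- function(Xp, kind, y) {
  fits <- list()
  if (any(kind == "continuous")) {
    fits$gaussian <- nb_gaussian(Xp[, kind == "continuous", drop = FALSE], y)
  }
  if (any(kind == "discrete")) {
    fits$multinomial <- nb_multinomial(Xp[, kind == "discrete", drop = FALSE],
                                       y)
  }
  if (any(kind == "binary")) {
    fits$bernoulli <- nb_bernoulli(Xp[, kind == "binary", drop = FALSE], y)
  }
  fits
}

base_learner_outputs <- function(fits, Xp, kind, meta_input) {
  cols <- lapply(names(fits), function(nm) {
    sub <- switch(nm,
                  gaussian = Xp[, kind == "continuous", drop = FALSE],
                  multinomial = Xp[, kind == "discrete", drop = FALSE],
                  bernoulli = Xp[, kind == "binary", drop = FALSE])
    p <- predict(fits[[nm]], sub)[, "FBTP"]
    if (meta_input == "labels") as.numeric(p >= 0.5) else p
  })
  out <- do.call(cbind, cols)
  colnames(out) <- names(fits)
  out
}

#' Fit the stacked classifier on a training subset
#'
#' Base naive-Bayes learners are fit on the kind-partition of the training
#' rows (preprocessing -- imputation, standardization, code shifting -- is
#' fitted on those rows only). The meta-learner is trained on cross-fitted
#' base outputs: an inner stratified 5-fold split of the training rows
#' supplies out-of-fold posteriors, so the meta-learner never sees
#' resubstitution predictions.
#'
#' @param table a \code{\link{feature_table}} containing the spec's features.
#' @param labels factor FBTP/NFBTP; default \code{table$labels}.
#' @param spec a \code{\link{stacked_model_spec}}.
#' @param train_rows training row indices.
#' @return object of class \code{"stacked_model"}; predict with
#'   \code{\link{predict.stacked_model}}.
#' @export
fit_stacked <- function(table, labels = table$labels, spec,
                        train_rows = seq_len(nrow(table$data))) {
  stopifnot(inherits(table, "feature_table"),
            inherits(spec, "stacked_model_spec"))
  labels <- factor(labels, levels = c("FBTP", "NFBTP"))
  feats <- intersect(spec$features, table$specs$name)
  if (length(feats) == 0) stop("no usable features in spec", call. = FALSE)
  specs <- table$specs[match(feats, table$specs$name), , drop = FALSE]
  ytr <- labels[train_rows]
  if (nlevels(droplevels(ytr)) < 2) {
    maj <- names(which.max(table(ytr)))
    warning("single-class training set; majority-label fallback",
            call. = FALSE)
    return(structure(list(fallback = maj), class = "stacked_model"))
  }
  prep <- fit_preprocessor(table$data, specs, train_rows)
  Xtr <- apply_preprocessor(prep, table$data, train_rows)
  kind <- specs$kind
  fits <- base_learner_fits(Xtr, kind, ytr)

  # cross-fitted meta-training inputs
  k <- min(spec$inner_folds, min(table(ytr)))
  meta_X <- matrix(NA_real_, length(train_rows), length(fits),
                   dimnames = list(NULL, names(fits)))
  if (k >= 2) {
    fold <- stratified_folds(ytr, k, seed = spec$seed)
    for (f in seq_len(k)) {
      inn <- fold != f
      if (nlevels(droplevels(ytr[inn])) < 2) next
      fits_f <- base_learner_fits(Xtr[inn, , drop = FALSE], kind, ytr[inn])
      meta_X[!inn, ] <- base_learner_outputs(
        fits_f, Xtr[!inn, , drop = FALSE], kind, spec$meta_input)
    }
  }
  miss <- apply(meta_X, 1, anyNA)
  if (any(miss)) { # degenerate inner split: resubstitution outputs fill in
    meta_X[miss, ] <- base_learner_outputs(
      fits, Xtr[miss, , drop = FALSE], kind, spec$meta_input)
  }

  meta_fit <- if (spec$meta == "svm_sigmoid") {
    set.seed(spec$seed)
    e1071::svm(x = meta_X, y = ytr, kernel = "sigmoid", scale = FALSE)
  } else {
    df <- data.frame(meta_X)
    glm(y ~ ., data = cbind(df, y = as.integer(ytr == "FBTP")),
        family = binomial())
  }
  structure(list(spec = spec, prep = prep, kind = kind, fits = fits,
                 meta_fit = meta_fit, features = feats),
            class = "stacked_model")
}

#' Predict from a fitted stacked model
#'
#' @param object a \code{"stacked_model"}.
#' @param newdata a \code{\link{feature_table}} or data.frame with the
#'   model's feature columns.
#' @param rows row indices of \code{newdata} to predict (default all).
#' @param ... unused.
#' @return data.frame: \code{label} (factor FBTP/NFBTP) and \code{score}
#'   (higher = more FBTP-like; SVM decision value or logistic probability).
#' @export
predict.stacked_model <- function(object, newdata, rows = NULL, ...) {
  data <- if (inherits(newdata, "feature_table")) newdata$data else
    as.data.frame(newdata)
  if (is.null(rows)) rows <- seq_len(nrow(data))
  if (!is.null(object$fallback)) {
    return(data.frame(
      label = factor(rep(object$fallback, length(rows)),
                     levels = c("FBTP", "NFBTP")),
      score = rep(0, length(rows))))
  }
  Xp <- apply_preprocessor(object$prep, data, rows)
  meta_X <- base_learner_outputs(object$fits, Xp, object$kind,
                                 object$spec$meta_input)
  if (object$spec$meta == "svm_sigmoid") {
    pred <- predict(object$meta_fit, meta_X, decision.values = TRUE)
    dv <- as.numeric(attr(pred, "decision.values"))
    # orient the decision value so higher = FBTP
    flip <- grepl("^NFBTP", colnames(attr(pred, "decision.values"))[1])
    data.frame(label = factor(as.character(pred),
                              levels = c("FBTP", "NFBTP")),
               score = if (flip) -dv else dv)
  } else {
    p <- predict(object$meta_fit, data.frame(meta_X), type = "response")
    data.frame(label = factor(ifelse(p >= 0.5, "FBTP", "NFBTP"),
                              levels = c("FBTP", "NFBTP")),
               score = as.numeric(p))
  }
}

#' Leave-one-out cross-validation of a stacked model
#'
#' One fold per sample; all preprocessing and every learner are refit within
#' each fold's training set. Per-fold predictions are pooled into a single
#' confusion matrix (per-fold averaging of precision is undefined for size-1
#' test sets) and summarized by \code{\link{compute_metrics}}.
#'
#' @param table a \code{\link{feature_table}}.
#' @param labels factor FBTP/NFBTP; default \code{table$labels}.
#' @param spec a \code{\link{stacked_model_spec}}.
#' @return list of class \code{"cv_metrics"}: \code{metrics}, \code{counts},
#'   \code{folds} (per-fold row, truth, prediction, score),
#'   \code{aggregation = "pooled"}.
#' @export
loocv_evaluate <- function(table, labels = table$labels, spec) {
  stopifnot(inherits(table, "feature_table"))
  labels <- factor(labels, levels = c("FBTP", "NFBTP"))
  n <- nrow(table$data)
  if (n < 3) stop("need at least 3 samples for LOOCV", call. = FALSE)
  folds <- lapply(seq_len(n), function(i) {
    model <- fit_stacked(table, labels, spec,
                         train_rows = setdiff(seq_len(n), i))
    pr <- predict(model, table, rows = i)
    data.frame(fold = i, row = i, truth = as.character(labels[i]),
               pred = as.character(pr$label), score = pr$score,
               stringsAsFactors = FALSE)
  })
  folds <- do.call(rbind, folds)
  counts <- confusion_counts(folds$truth, folds$pred)
  structure(list(metrics = compute_metrics(counts), counts = counts,
                 folds = folds, aggregation = "pooled"),
            class = "cv_metrics")
}

#' @export
print.cv_metrics <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "pooled CV metrics (%d folds): accuracy %.3f, precision %.3f, recall %.3f, F1 %.3f\n",
    nrow(x$folds), m$accuracy, m$precision, m$recall, m$f1))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Baseline battery

baseline_model_fits <- function(name, Xtr, ytr, Xte, seed) {
  yf <- droplevels(ytr)
  switch(name,
    logistic = {
      beta <- robust_logistic_coefs(Xtr, yf)
      # rebuild linear predictor incl. intercept via refit for prediction
      p <- ncol(Xtr)
      if (p + 1 < nrow(Xtr)) {
        df <- data.frame(Xtr)
        fit <- suppressWarnings(glm(
          y ~ ., data = cbind(df, y = as.integer(yf == "FBTP")),
          family = binomial()))
        pr <- predict(fit, data.frame(Xte), type = "response")
      } else {
        fit <- glmnet::glmnet(Xtr, as.integer(yf == "FBTP"),
                              family = "binomial", alpha = 0, lambda = 1e-2)
        pr <- as.numeric(predict(fit, Xte, type = "response"))
      }
      ifelse(pr >= 0.5, "FBTP", "NFBTP")
    },
    random_forest = {
      set.seed(seed)
      fit <- randomForest::randomForest(Xtr, yf, ntree = 250)
      as.character(predict(fit, Xte))
    },
    xgboost = {
      set.seed(seed)
      dtrain <- xgboost::xgb.DMatrix(Xtr, label = as.integer(yf == "FBTP"),
                                     nthread = 1)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 3,
                      eta = 0.3, nthread = 1),
        data = dtrain, nrounds = 30, verbose = 0)
      pr <- predict(fit, xgboost::xgb.DMatrix(Xte, nthread = 1))
      ifelse(pr >= 0.5, "FBTP", "NFBTP")
    },
    decision_tree = {
      df <- data.frame(Xtr, y = yf)
      fit <- rpart::rpart(y ~ ., data = df, method = "class")
      as.character(predict(fit, data.frame(Xte), type = "class"))
    },
    knn = {
      as.character(class::knn(Xtr, Xte, yf, k = min(5, nrow(Xtr))))
    },
    svm = {
      set.seed(seed)
      fit <- e1071::svm(Xtr, yf, kernel = "radial", scale = FALSE)
      as.character(predict(fit, Xte))
    },
    naive_bayes = {
      fit <- nb_gaussian(Xtr, yf)
      p <- predict(fit, Xte)
      colnames(p)[max.col(p, ties.method = "first")]
    },
    stop("unknown baseline ", name))
}

#' Compare the seven baseline classifiers by stratified k-fold CV
#'
#' Logistic regression, random forest, gradient-boosted trees, decision
#' tree, k-nearest-neighbor, support-vector machine and (Gaussian) naive
#' Bayes, each evaluated on the same seeded stratified folds. Continuous
#' features are standardized with statistics fitted inside each training
#' fold.
#'
#' @param table a \code{\link{feature_table}}.
#' @param labels factor FBTP/NFBTP; default \code{table$labels}.
#' @param k number of folds (default 5).
#' @param seed integer seed controlling fold assignment and model inits.
#' @param features optional subset of feature names (default: all).
#' @return data.frame: model, accuracy, precision, recall, f1 (pooled over
#'   folds); per-fold predictions in \code{attr(, "folds")}.
#' @export
compare_baselines <- function(table, labels = table$labels, k = 5, seed = 1L,
                              features = NULL) {
  stopifnot(inherits(table, "feature_table"))
  labels <- factor(labels, levels = c("FBTP", "NFBTP"))
  if (is.null(features)) features <- table$specs$name
  specs <- table$specs[match(features, table$specs$name), , drop = FALSE]
  n <- nrow(table$data)
  stopifnot(n >= k)
  fold <- stratified_folds(labels, k, seed)
  models <- c("logistic", "random_forest", "xgboost", "decision_tree",
              "knn", "svm", "naive_bayes")
  preds <- matrix(NA_character_, n, length(models),
                  dimnames = list(NULL, models))
  for (f in seq_len(k)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    if (nlevels(droplevels(labels[tr])) < 2) {
      stop("fold ", f, " training set lost a class; use fewer folds",
           call. = FALSE)
    }
    prep <- fit_preprocessor(table$data, specs, tr)
    Xtr <- apply_preprocessor(prep, table$data, tr)
    Xte <- apply_preprocessor(prep, table$data, te)
    for (m in models) {
      preds[te, m] <- baseline_model_fits(m, Xtr, labels[tr], Xte,
                                          seed = seed + f)
    }
  }
  rows <- lapply(models, function(m) {
    met <- compute_metrics(confusion_counts(labels, preds[, m]))
    data.frame(model = m, accuracy = met$accuracy, precision = met$precision,
               recall = met$recall, f1 = met$f1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "folds") <- data.frame(row = seq_len(n), fold = fold,
                                   truth = as.character(labels), preds)
  out
}

#' Grid search over feature-count prefixes and meta-learners
#'
#' Scans prefixes of the consensus-ordered selected features (1 up to
#' \code{feature_budget}, respecting the kind mix of the selection) crossed
#' with the meta-learner options, evaluating each candidate by LOOCV.
#' Selection prioritizes precision (the costly error being treating a
#' patient who will not fully benefit), with accuracy then fewer features as
#' tie-breaks.
#'
#' @param table a \code{\link{feature_table}}.
#' @param labels factor FBTP/NFBTP; default \code{table$labels}.
#' @param ordered_features candidate features, most important first (e.g.
#'   from \code{\link{select_features}} ordered by consensus score).
#' @param feature_budget maximum prefix length (default 50).
#' @param meta_options meta-learners to try.
#' @param seed integer seed.
#' @return list: \code{best_spec} (a \code{\link{stacked_model_spec}}),
#'   \code{best_metrics}, \code{scan} (one row per candidate).
#' @export
grid_search_config <- function(table, labels = table$labels, ordered_features,
                               feature_budget = 50,
                               meta_options = c("svm_sigmoid", "logistic"),
                               seed = 1L) {
  if (length(ordered_features) == 0) {
    stop("empty candidate feature set", call. = FALSE)
  }
  sizes <- seq_len(min(feature_budget, length(ordered_features)))
  scan <- list()
  for (meta in meta_options) {
    for (s in sizes) {
      spec <- stacked_model_spec(head(ordered_features, s), meta = meta,
                                 seed = seed)
      cv <- loocv_evaluate(table, labels, spec)
      scan[[length(scan) + 1]] <- data.frame(
        meta = meta, n_features = s, accuracy = cv$metrics$accuracy,
        precision = cv$metrics$precision, recall = cv$metrics$recall,
        f1 = cv$metrics$f1, stringsAsFactors = FALSE)
    }
  }
  scan <- do.call(rbind, scan)
  best <- scan[order(-scan$precision, -scan$accuracy, scan$n_features,
                     scan$meta), ][1, ]
  best_spec <- stacked_model_spec(head(ordered_features, best$n_features),
                                  meta = best$meta, seed = seed)
  list(best_spec = best_spec,
       best_metrics = as.list(best[c("accuracy", "precision", "recall",
                                     "f1")]),
       scan = scan)
}
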