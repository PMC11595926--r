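# Data model, cleaning, encoding and response labeling: raw per-patient
# records -> analysis-ready typed feature table.

#' Parse possibly censored numeric text
#'
#' Clinical PSA columns contain detection-limit entries such as \code{">1200"}
#' or \code{"<0.006"}. The numeric bound itself is returned, together with a
#' censoring flag (\code{"right"}, \code{"left"} or \code{"none"}). For the
#' 50\%-reduction response rule this bound substitution is label-safe on the
#' published cohort: no monotone imputation of the censored values can flip a
#' label.
#'
#' @param text character vector; each element a number optionally prefixed by
#'   \code{"<"} or \code{">"}. \code{NA} propagates.
#' @return list with numeric \code{value} and character \code{censor}, both the
#'   length of \code{text}.
#' @examples
#' parse_censored_value(c(">1200", "<0.006", "28.1"))
#' @export
parse_censored_value <- function(text) {
  text <- as.character(text)
  raw <- trimws(text)
  censor <- rep("none", length(raw))
  censor[startsWith(raw, "<")] <- "left"
  censor[startsWith(raw, ">")] <- "right"
  stripped <- sub("^[<>]", "", raw)
  value <- suppressWarnings(as.numeric(stripped))
  bad <- which(!is.na(raw) & is.na(value))
  if (length(bad) > 0) {
    stop("non-numeric value(s) at position(s) ", paste(bad, collapse = ", "),
         ": ", paste(sQuote(raw[bad]), collapse = ", "), call. = FALSE)
  }
  censor[is.na(raw)] <- NA_character_
  list(value = value, censor = censor)
}

#' Label treatment response (FBTP vs NFBTP)
#'
#' A patient is a fully beneficial treatment patient (FBTP) when all six
#' therapy cycles were completed and the final PSA is at most half the
#' baseline PSA (a reduction of at least 50\%, boundary inclusive). Everyone
#' else -- fewer than six cycles, or a smaller reduction, or a rise -- is a
#' not fully beneficial treatment patient (NFBTP).
#'
#' @param psa_before,psa_after baseline and final serum PSA (ng/mL),
#'   non-negative; \code{psa_before} must be strictly positive (a zero
#'   baseline leaves the relative reduction undefined).
#' @param n_cycles number of completed therapy cycles, integer in 1..6.
#' @return factor with levels \code{c("FBTP", "NFBTP")}.
#' @examples
#' label_response(385, 28.1, 6)    # FBTP
#' label_response(92.77, 15.86, 2) # NFBTP: only 2 cycles
#' @export
label_response <- function(psa_before, psa_after, n_cycles) {
  n <- max(length(psa_before), length(psa_after), length(n_cycles))
  psa_before <- rep_len(psa_before, n)
  psa_after <- rep_len(psa_after, n)
  n_cycles <- rep_len(n_cycles, n)
  if (any(psa_before == 0, na.rm = TRUE)) {
    stop("psa_before == 0: relative PSA reduction is undefined", call. = FALSE)
  }
  if (any(psa_before < 0 | psa_after < 0, na.rm = TRUE)) {
    stop("PSA values must be non-negative", call. = FALSE)
  }
  if (any(n_cycles < 1 | n_cycles > 6 | n_cycles != round(n_cycles),
          na.rm = TRUE)) {
    stop("n_cycles must be an integer in [1, 6]", call. = FALSE)
  }
  fb <- n_cycles == 6 & psa_after <= 0.5 * psa_before
  factor(ifelse(fb, "FBTP", "NFBTP"), levels = c("FBTP", "NFBTP"))
}

#' Encode tracer discordance as a small integer code
#'
#' Lesion-level disagreement between two PET tracers (e.g. PSMA vs FDG) is
#' coded: -1 if either status is missing, 0 if concordant, 1 if the first
#' tracer is negative and the second positive, 2 if the first is positive and
#' the second negative.
#'
#' @param tracer_a_status,tracer_b_status character vectors over
#'   \code{"+"}, \code{"-"}; \code{NA} or \code{"missing"} mean no scan.
#' @return integer vector of codes in \{-1, 0, 1, 2\}.
#' @examples
#' encode_tracer_discordance(c(NA, "+", "-"), c("+", "+", "+"))
#' @export
encode_tracer_discordance <- function(tracer_a_status, tracer_b_status) {
  norm <- function(s) {
    s <- as.character(s)
    s[!is.na(s) & s == "missing"] <- NA_character_
    bad <- !is.na(s) & !s %in% c("+", "-")
    if (any(bad)) {
      stop("tracer status must be '+', '-', 'missing' or NA; got ",
           paste(sQuote(unique(s[bad])), collapse = ", "), call. = FALSE)
    }
    s
  }
  a <- norm(tracer_a_status)
  b <- norm(tracer_b_status)
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  code <- integer(n)
  code[is.na(a) | is.na(b)] <- -1L
  ok <- !is.na(a) & !is.na(b)
  code[ok & a == b] <- 0L
  code[ok & a == "-" & b == "+"] <- 1L
  code[ok & a == "+" & b == "-"] <- 2L
  code
}

# ---------------------------------------------------------------------------
# FeatureTable: a patient-by-feature data.frame plus per-feature type specs.

#' Construct a per-feature specification table
#'
#' Each feature carries a kind deciding which base classifier consumes it
#' downstream (\code{continuous} -> Gaussian NB, \code{discrete} ->
#' multinomial NB, \code{binary} -> Bernoulli NB), an encoding tag, and a
#' nominal flag routing it to the chi-square screen instead of Mann-Whitney.
#'
#' @param name character feature names (unique).
#' @param kind one of \code{"continuous"}, \code{"discrete"}, \code{"binary"}
#'   per feature.
#' @param encoding one of \code{"none"}, \code{"zscore"}, \code{"ordinal"},
#'   \code{"onehot"} per feature (recycled).
#' @param nominal logical; \code{TRUE} for unordered categorical codes
#'   (recycled, default \code{FALSE}; \code{binary} features are always
#'   treated as nominal for screening).
#' @return data.frame of class \code{"feature_spec"}.
#' @export
feature_spec <- function(name, kind, encoding = "none", nominal = FALSE) {
  name <- as.character(name)
  if (anyDuplicated(name)) stop("duplicate feature names", call. = FALSE)
  kind <- match.arg(kind, c("continuous", "discrete", "binary"),
                    several.ok = TRUE)
  kind <- rep_len(kind, length(name))
  encoding <- rep_len(encoding, length(name))
  stopifnot(all(encoding %in% c("none", "zscore", "ordinal", "onehot")))
  nominal <- rep_len(as.logical(nominal), length(name))
  out <- data.frame(name = name, kind = kind, encoding = encoding,
                    nominal = nominal, stringsAsFactors = FALSE)
  class(out) <- c("feature_spec", "data.frame")
  out
}

#' Bundle a feature matrix with its specs and optional labels
#'
#' @param data data.frame of numeric feature columns (rows = patients).
#' @param specs \code{\link{feature_spec}} covering exactly the columns of
#'   \code{data} (order taken from \code{data}).
#' @param labels optional factor with levels \code{c("FBTP","NFBTP")}.
#' @return list of class \code{"feature_table"} with elements \code{data},
#'   \code{specs}, \code{labels}.
#' @export
feature_table <- function(data, specs, labels = NULL) {
  data <- as.data.frame(data)
  if (!inherits(specs, "feature_spec")) {
    stop("specs must be a feature_spec", call. = FALSE)
  }
  if (!setequal(names(data), specs$name)) {
    stop("specs must cover exactly the columns of data", call. = FALSE)
  }
  specs <- specs[match(names(data), specs$name), , drop = FALSE]
  rownames(specs) <- NULL
  if (!is.null(labels)) {
    labels <- factor(labels, levels = c("FBTP", "NFBTP"))
    if (length(labels) != nrow(data)) {
      stop("labels length must equal nrow(data)", call. = FALSE)
    }
  }
  structure(list(data = data, specs = specs, labels = labels),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$data), "patients x", ncol(x$data),
      "features\n")
  cat("  kinds:", paste(names(table(x$specs$kind)), table(x$specs$kind),
                        sep = "=", collapse = ", "), "\n")
  if (!is.null(x$labels)) {
    cat("  labels:", paste(levels(x$labels), table(x$labels), sep = "=",
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' Column names of a given kind
#' @param table a \code{\link{feature_table}}.
#' @param kind \code{"continuous"}, \code{"discrete"} or \code{"binary"}.
#' @return character vector of feature names.
#' @export
features_of_kind <- function(table, kind) {
  table$specs$name[table$specs$kind == kind]
}

# ---------------------------------------------------------------------------
# Standardization and encoding

#' Fit Z-score statistics on a row subset and transform
#'
#' Standardizes continuous columns to mean 0 / SD 1 using statistics computed
#' on \code{fit_rows} only, so held-out rows can be transformed without
#' leakage. The population-SD convention (divisor n) is the default; the
#' sample convention (n - 1) is available via \code{ddof}.
#'
#' @param x numeric matrix or data.frame of continuous columns.
#' @param fit_rows integer/logical row subset the statistics are computed on
#'   (default: all rows).
#' @param ddof 0 for population SD (default) or 1 for sample SD.
#' @return list of class \code{"zscore_fit"}: \code{center}, \code{scale},
#'   \code{ddof}, and \code{transformed} (all rows transformed).
#' @export
zscore_fit_transform <- function(x, fit_rows = seq_len(nrow(x)), ddof = 0) {
  x <- as.matrix(x)
  stopifnot(ddof %in% c(0, 1), length(fit_rows) > 0)
  xf <- x[fit_rows, , drop = FALSE]
  center <- colMeans(xf, na.rm = TRUE)
  ssd <- apply(xf, 2, function(col) {
    col <- col[!is.na(col)]
    n <- length(col)
    if (n <= ddof) return(NA_real_)
    sqrt(sum((col - mean(col))^2) / (n - ddof))
  })
  zero <- which(!is.na(ssd) & ssd == 0)
  if (length(zero) > 0) {
    stop("constant column(s) over fit rows: ",
         paste(colnames(x)[zero], collapse = ", "),
         " -- drop these features before standardizing", call. = FALSE)
  }
  fit <- structure(list(center = center, scale = ssd, ddof = ddof),
                   class = "zscore_fit")
  fit$transformed <- zscore_apply(fit, x)
  fit
}

#' Apply or invert fitted Z-score statistics
#' @param fit a \code{"zscore_fit"}.
#' @param x matrix/data.frame with the fitted columns.
#' @return transformed (or back-transformed) matrix.
#' @export
zscore_apply <- function(fit, x) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, fit$center[colnames(x)]), 2, fit$scale[colnames(x)], "/")
}

#' @rdname zscore_apply
#' @export
zscore_invert <- function(fit, x) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, fit$scale[colnames(x)], "*"), 2, fit$center[colnames(x)],
        "+")
}

#' Encode a categorical column
#'
#' Ordinal encoding maps the declared level order to integers 0..k-1; one-hot
#' encoding expands to k binary columns named \code{feature=level} whose rows
#' sum to 1. The level order comes from the declared \code{levels} (clinical
#' order), never from the data.
#'
#' @param column vector of category values.
#' @param scheme \code{"ordinal"} or \code{"onehot"}.
#' @param levels category levels in order; default: sorted unique values.
#' @param name feature name used for one-hot column names.
#' @return ordinal: integer vector (NA preserved); onehot: integer matrix.
#' @export
encode_categorical <- function(column, scheme = c("ordinal", "onehot"),
                               levels = NULL, name = "x") {
  scheme <- match.arg(scheme)
  if (is.null(levels)) levels <- sort(unique(column[!is.na(column)]))
  unseen <- setdiff(unique(column[!is.na(column)]), levels)
  if (length(unseen) > 0) {
    stop("unseen categor", if (length(unseen) > 1) "ies" else "y",
         " in ", sQuote(name), ": ",
         paste(sQuote(unseen), collapse = ", "), call. = FALSE)
  }
  idx <- match(column, levels)
  if (scheme == "ordinal") return(idx - 1L)
  if (length(levels) == 1) {
    warning("one-hot encoding a single-level column ", sQuote(name),
            call. = FALSE)
  }
  out <- matrix(0L, nrow = length(column), ncol = length(levels),
                dimnames = list(NULL, paste0(name, "=", levels)))
  out[cbind(seq_along(column), idx)] <- 1L
  out[is.na(idx), ] <- NA_integer_
  out
}

#' Fit and apply training-fold median imputation
#'
#' Continuous features: training-rows median. Discrete/binary codes: the
#' explicit missing level -1 (mirroring the tracer-discordance convention) via
#' \code{strategy = "code"}.
#'
#' @param x numeric vector.
#' @param fit_rows rows the median is computed on.
#' @param strategy \code{"median"} or \code{"code"}.
#' @return vector with NAs filled.
#' @export
impute_missing <- function(x, fit_rows = seq_along(x),
                           strategy = c("median", "code")) {
  strategy <- match.arg(strategy)
  fill <- if (strategy == "median") median(x[fit_rows], na.rm = TRUE) else -1
  x[is.na(x)] <- fill
  x
}

# ---------------------------------------------------------------------------
# Packaged published cohort (the printed per-patient clinical table)

#' Load the packaged 25-patient clinical cohort
#'
#' The published per-patient clinical characteristics (age, WHO performance
#' status, Gleason score, PSA before/after therapy, number of completed
#' cycles) shipped as a plain CSV. Censored PSA entries are parsed to their
#' bounds with censoring flags, and the response label is derived.
#'
#' @return data.frame with numeric PSA columns, \code{psa_after_censor}
#'   flags, and a \code{label} factor (11 FBTP, 14 NFBTP).
#' @export
load_clinical_cohort <- function() {
  path <- system.file("extdata", "clinical_cohort.csv", package = "rltstack",
                      mustWork = TRUE)
  raw <- read.csv(path, colClasses = "character")
  pb <- parse_censored_value(raw$psa_before)
  pa <- parse_censored_value(raw$psa_after)
  out <- data.frame(
    patient_id = raw$patient_id,
    age = as.numeric(raw$age),
    who = as.integer(raw$who),
    gleason = suppressWarnings(as.integer(raw$gleason)),
    psa_before = pb$value,
    psa_before_censor = pb$censor,
    psa_after = pa$value,
    psa_after_censor = pa$censor,
    n_cycles = as.integer(raw$n_cycles),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$patient_id)) stop("duplicate patient ids")
  out$label <- label_response(out$psa_before, out$psa_after, out$n_cycles)
  out
}

#' Age summary of the packaged cohort
#'
#' Reports both the arithmetic mean and the sample median of the age column;
#' the source publication labels 72.1 years a "median age", yet 72.1 is the
#' column's mean while its median is 74, so both are returned without
#' adjudicating.
#'
#' @param age numeric ages; default: the packaged cohort's.
#' @return named list with \code{mean} and \code{median}.
#' @export
age_summary <- function(age = load_clinical_cohort()$age) {
  list(mean = mean(age), median = median(age))
}
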