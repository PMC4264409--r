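# Reading-time preprocessing: absolute trimming, log transform,
# residualization against word length and log list position, and sum
# coding of the factorial design.

#' Trim implausible raw reading times
#'
#' Removes rows with raw RT outside `[lower, upper]` milliseconds.  No
#' accuracy-based exclusion is performed: all trials are analyzed
#' regardless of comprehension accuracy.
#'
#' @param data SPR dataset with an `rt` column.
#' @param lower,upper Bounds in ms (defaults 100 and 5000).
#' @return A list with `data` (trimmed) and `removed_fraction`.
#' @examples
#' trim_rts(data.frame(rt = c(50, 200, 6000)))$removed_fraction  # 2/3
#' @export
trim_rts <- function(data, lower = 100, upper = 5000) {
  if (!"rt" %in% names(data)) stop("`data` must have an `rt` column")
  if (!(lower >= 0 && lower < upper)) stop("need 0 <= lower < upper")
  keep <- data$rt >= lower & data$rt <= upper
  out <- data[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("trimming removed every row")
  list(data = out, removed_fraction = 1 - mean(keep))
}

#' Residualize log reading times
#'
#' Regresses log RT on word length and log list position over the whole
#' fit sample (fillers included, to get maximally general estimates),
#' with per-participant intercept adjustments, and attaches the
#' residuals as column `resid_log_rt` — the dependent variable of the
#' downstream region analyses.
#'
#' @param data Trimmed SPR dataset (fillers included).
#' @param method `"mixed"` (default) uses a linear mixed model with a
#'   by-participant random intercept (shrinkage estimator, via
#'   \pkg{lme4}); `"by_participant"` uses fixed per-participant
#'   intercepts in ordinary least squares.  The two agree closely at
#'   realistic sample sizes.
#' @return `data` with a `resid_log_rt` column added.  The fitted
#'   word-length and log-list-position coefficients are attached as
#'   attribute `"coefficients"`.
#' @export
residualize <- function(data, method = c("mixed", "by_participant")) {
  method <- match.arg(method)
  needed <- c("rt", "word_length", "list_position", "participant")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    stop("`data` is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (length(unique(data$participant)) < 2L) {
    stop("degenerate fit: need at least two participants")
  }
  if (stats::var(data$word_length) == 0 || stats::var(log(data$list_position)) == 0) {
    stop("degenerate fit: constant predictor")
  }
  df <- data.frame(log_rt = log(data$rt), word_length = data$word_length,
                   log_pos = log(data$list_position),
                   participant = factor(data$participant))
  if (method == "mixed") {
    fit <- lme4::lmer(log_rt ~ word_length + log_pos + (1 | participant),
                      data = df, REML = TRUE,
                      control = lme4::lmerControl(calc.derivs = FALSE))
    data$resid_log_rt <- stats::residuals(fit)
    coefs <- lme4::fixef(fit)[c("word_length", "log_pos")]
  } else {
    fit <- stats::lm(log_rt ~ word_length + log_pos + participant, data = df)
    data$resid_log_rt <- stats::residuals(fit)
    coefs <- stats::coef(fit)[c("word_length", "log_pos")]
  }
  attr(data, "coefficients") <- coefs
  data
}

#' Sum-code a two-level factor
#'
#' Maps the two levels to -1/+1.  The "marked" level (`positive`) gets
#' +1; by convention `complex` and `green` are the marked levels, so
#' facilitation from elaboration shows up as a negative coefficient and
#' is read off `P(beta < 0)`.  Interactions are products of the coded
#' columns.
#'
#' @param x Character or factor vector with exactly two distinct levels.
#' @param positive The level mapped to +1; defaults to `"complex"` or
#'   `"green"` when present, otherwise the last level alphabetically.
#' @return Numeric vector of -1/+1.
#' @examples
#' sum_code(c("simple", "complex", "simple"))
#' @export
sum_code <- function(x, positive = NULL) {
  lv <- sort(unique(as.character(x)))
  if (length(lv) != 2L) {
    stop("sum coding supports exactly two levels; got ", length(lv))
  }
  if (is.null(positive)) {
    positive <- if ("complex" %in% lv) "complex" else if ("green" %in% lv) "green" else lv[2]
  }
  if (!positive %in% lv) stop("`positive` is not a level of `x`")
  ifelse(as.character(x) == positive, 1, -1)
}

# Split the condition label "a_b" into two sum-coded columns plus their
# interaction, with field-conventional factor names.
.design_columns <- function(condition) {
  parts <- strsplit(as.character(condition), "_")
  bad <- vapply(parts, length, integer(1)) != 2L
  if (any(bad)) {
    stop("condition labels must be of the form '<factor1>_<factor2>'")
  }
  f1 <- vapply(parts, `[`, character(1), 1)
  f2 <- vapply(parts, `[`, character(1), 2)
  lv1 <- sort(unique(f1)); lv2 <- sort(unique(f2))
  names2 <- if (setequal(lv1, c("complex", "simple"))) {
    c("NP1_complexity", "NP2_complexity")
  } else if (setequal(lv1, c("green", "white"))) {
    c("noun_color", "verb_color")
  } else c("factor1", "factor2")
  x1 <- sum_code(f1); x2 <- sum_code(f2)
  out <- cbind(x1, x2, x1 * x2)
  colnames(out) <- c(names2, paste(names2, collapse = " x "))
  out
}
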