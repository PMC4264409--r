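#' @keywords internal
"_PACKAGE"

# Reserved token marking a degraded/blurry feature slot.  Permitted in
# retrieval probes; stored traces acquire it only through encoding
# interference (see apply_encoding_interference).
WILDCARD <- "?"

#' Validate a feature vector
#'
#' A feature vector is an ordered character vector of symbolic feature
#' tokens; each position is one feature slot.  The reserved token `"?"`
#' marks a degraded (blurry) slot and is permitted only in retrieval
#' probes, not in stored traces supplied by the user.
#'
#' @param x Character vector of feature tokens.
#' @param probe Logical; if `TRUE`, `"?"` slots are allowed.
#' @param arg Name used in error messages.
#' @return `x`, invisibly, after validation.
#' @examples
#' feature_vector(c("C", "C", "2", "3", "1"))
#' feature_vector(c("C", "C", "?", "2", "3"), probe = TRUE)
#' @export
feature_vector <- function(x, probe = FALSE, arg = "x") {
  if (!is.character(x) || length(x) < 1L) {
    stop(sprintf("`%s` must be a character vector with at least one feature", arg))
  }
  if (any(is.na(x)) || any(!nzchar(x))) {
    stop(sprintf("`%s` contains empty or missing feature tokens", arg))
  }
  if (!probe && any(x == WILDCARD)) {
    stop(sprintf("`%s`: the degraded-slot token \"?\" is only permitted in probes", arg))
  }
  invisible(x)
}

#' Count mismatching features between a probe and a candidate trace
#'
#' Comparison is positional (slot-aligned) and asymmetric: only the
#' probe's slots are compared, so it is the number of features in the
#' probe that determines how many mismatches there can be.  A probe slot
#' with no counterpart in the candidate counts as a mismatch; candidate
#' features beyond the probe's length are ignored.
#'
#' Degraded slots: a `"?"` in the probe is scored according to
#' `wildcard`: under `"mismatch"` (default) a blurry slot fails to
#' support any match and counts as a mismatch; under `"exclude"` the
#' slot is dropped from the comparison altogether (it also shrinks the
#' denominator of [feature_distance()]).  A `"?"` in the candidate (a
#' feature lost to overwriting) matches nothing.
#'
#' @param probe Character vector; the retrieval probe.
#' @param candidate Character vector; a stored trace.
#' @param wildcard How to score `"?"` slots in the probe:
#'   `"mismatch"` or `"exclude"`.
#' @return Non-negative integer count of mismatches.
#' @examples
#' count_mismatches(c("C","C","2","3","1"), c("C","C","1","2","3"))  # 3
#' count_mismatches(c("C","C","2","3","1","Q","R","N"),
#'                  c("C","C","1","2","3"))                          # 6
#' @export
count_mismatches <- function(probe, candidate,
                             wildcard = c("mismatch", "exclude")) {
  wildcard <- match.arg(wildcard)
  feature_vector(probe, probe = TRUE, arg = "probe")
  feature_vector(candidate, probe = TRUE, arg = "candidate")
  keep <- if (wildcard == "exclude") probe != WILDCARD else rep(TRUE, length(probe))
  p <- probe[keep]
  if (length(p) == 0L) return(0L)
  idx <- seq_along(probe)[keep]
  cand <- candidate[idx]            # NA where the probe outruns the candidate
  match_ok <- !is.na(cand) & cand == p & p != WILDCARD & cand != WILDCARD
  sum(!match_ok)
}

#' Feature distance between probe and candidate
#'
#' The number of mismatching features divided by the number of compared
#' features.  Under the probe-denominator rule the compared features are
#' the probe's slots (minus any `"?"` slots if `wildcard = "exclude"`).
#'
#' @inheritParams count_mismatches
#' @return Real number in \[0, 1\].
#' @examples
#' feature_distance(c("C","C","2","3","1"), c("C","C","1","2","3"))  # 0.6
#' @export
feature_distance <- function(probe, candidate,
                             wildcard = c("mismatch", "exclude")) {
  wildcard <- match.arg(wildcard)
  m <- count_mismatches(probe, candidate, wildcard)
  n_compared <- if (wildcard == "exclude") sum(probe != WILDCARD) else length(probe)
  if (n_compared == 0L) {
    stop("no compared features: every probe slot is degraded and excluded")
  }
  m / n_compared
}

#' Feature similarity between probe and candidate
#'
#' `s = exp(-d)` where `d` is [feature_distance()].  Because `d` lies in
#' \[0, 1\], similarity lies in \[exp(-1), 1\].
#'
#' @inheritParams count_mismatches
#' @return Real number in \[exp(-1), 1\].
#' @examples
#' feature_similarity(c("C","C","2","3","1"), c("C","C","1","2","3"))  # 0.549
#' @export
feature_similarity <- function(probe, candidate,
                               wildcard = c("mismatch", "exclude")) {
  exp(-feature_distance(probe, candidate, wildcard))
}

#' Construct a retrieval scenario
#'
#' A retrieval scenario is one probe plus an ordered set of candidate
#' memory traces, one of which is designated the target.
#'
#' @param probe Character vector; the retrieval probe (may contain `"?"`).
#' @param traces List of character vectors; the candidate traces.
#' @param target_index Integer index of the target within `traces`.
#' @param name Optional scenario name.
#' @return An object of class `"retrieval_scenario"`.
#' @examples
#' sc <- retrieval_scenario(
#'   probe = c("C","C","2","3","1"),
#'   traces = list(c("C","C","1","2","3"), c("C","C","2","3","1"),
#'                 c("C","C","3","1","2")),
#'   target_index = 2)
#' sampling_probabilities(sc)
#' @export
retrieval_scenario <- function(probe, traces, target_index, name = NULL) {
  feature_vector(probe, probe = TRUE, arg = "probe")
  if (!is.list(traces) || length(traces) < 1L) {
    stop("`traces` must be a non-empty list of feature vectors")
  }
  for (i in seq_along(traces)) {
    feature_vector(traces[[i]], probe = TRUE, arg = sprintf("traces[[%d]]", i))
  }
  target_index <- as.integer(target_index)
  if (length(target_index) != 1L || is.na(target_index) ||
      target_index < 1L || target_index > length(traces)) {
    stop("`target_index` must index into `traces`")
  }
  structure(
    list(probe = probe, traces = traces, target_index = target_index,
         name = name),
    class = "retrieval_scenario"
  )
}

#' @export
print.retrieval_scenario <- function(x, ...) {
  cat("Retrieval scenario", if (!is.null(x$name)) paste0("'", x$name, "'"), "\n")
  cat("  probe :", paste(x$probe, collapse = " "), "\n")
  for (i in seq_along(x$traces)) {
    cat(sprintf("  %s %d: %s\n",
                if (i == x$target_index) "target " else "trace  ",
                i, paste(x$traces[[i]], collapse = " ")))
  }
  invisible(x)
}

#' Luce-ratio sampling probabilities for a retrieval scenario
#'
#' The probability of sampling trace `E_i` given probe `X` is its
#' similarity normalized by the summed similarity of all candidates:
#' `Pr(E_i | X) = s(X, E_i) / sum_j s(X, E_j)`.
#'
#' @param scenario A [retrieval_scenario()].
#' @param wildcard Probe `"?"` policy; see [count_mismatches()].
#' @param sim_digits If non-`NULL`, similarities are rounded to this many
#'   decimal places before normalization.  Printed model tables in the
#'   literature typically normalize the 2-d.p. similarities they display,
#'   so `sim_digits = 2` reproduces such tables cell-for-cell; the
#'   default (`NULL`) normalizes exact similarities.
#' @return A list of class `"sampling_result"` with elements
#'   `similarity` (per trace), `probability` (per trace, sums to 1) and
#'   `target_probability`.
#' @export
sampling_probabilities <- function(scenario,
                                   wildcard = c("mismatch", "exclude"),
                                   sim_digits = NULL) {
  wildcard <- match.arg(wildcard)
  stopifnot(inherits(scenario, "retrieval_scenario"))
  sims <- vapply(scenario$traces,
                 function(tr) feature_similarity(scenario$probe, tr, wildcard),
                 numeric(1))
  if (!is.null(sim_digits)) sims <- round(sims, sim_digits)
  probs <- sims / sum(sims)
  structure(
    list(similarity = sims, probability = probs,
         target_probability = probs[[scenario$target_index]],
         target_index = scenario$target_index),
    class = "sampling_result"
  )
}

#' @export
print.sampling_result <- function(x, ...) {
  df <- data.frame(trace = seq_along(x$similarity),
                   similarity = round(x$similarity, 4),
                   probability = round(x$probability, 4))
  df$target <- ifelse(df$trace == x$target_index, "*", "")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Read retrieval scenarios from a plain-text file
#'
#' One scenario per blank-line-separated record.  Each record contains
#' whitespace-separated token lines:
#' \preformatted{
#' name: intact-cue
#' probe: C C 2 3 1
#' trace: C C 1 2 3
#' trace: C C 2 3 1
#' trace: C C 3 1 2
#' target: 2
#' }
#' Lines starting with `#` are comments.  The two worked scenarios from
#' the redintegration model (an intact five-feature cue and an
#' elaborated eight-feature cue) ship with the package; see the example.
#'
#' @param path Path to a scenario file.
#' @return A list of [retrieval_scenario()] objects.
#' @examples
#' scens <- read_scenarios(system.file("extdata", "worked_scenarios.txt",
#'                                     package = "redint"))
#' sampling_probabilities(scens[[1]], sim_digits = 2)
#' @export
read_scenarios <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[!startsWith(lines, "#")]
  breaks <- cumsum(lines == "")
  records <- split(lines[lines != ""], breaks[lines != ""])
  out <- list()
  for (rec in records) {
    if (length(rec) == 0L) next
    fields <- sub(":.*$", "", rec)
    values <- trimws(sub("^[^:]*:", "", rec))
    bad <- !fields %in% c("name", "probe", "trace", "target")
    if (any(bad)) {
      stop("unrecognized scenario field(s): ", paste(unique(fields[bad]), collapse = ", "))
    }
    if (sum(fields == "probe") != 1L || !any(fields == "trace") ||
        sum(fields == "target") != 1L) {
      stop("each scenario record needs one probe, one target and at least one trace line")
    }
    toks <- function(v) strsplit(v, "[[:space:]]+")[[1]]
    out[[length(out) + 1L]] <- retrieval_scenario(
      probe = toks(values[fields == "probe"]),
      traces = lapply(values[fields == "trace"], toks),
      target_index = as.integer(values[fields == "target"]),
      name = if (any(fields == "name")) values[fields == "name"] else NULL
    )
  }
  out
}
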