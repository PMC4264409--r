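# Operationalizes the elaboration/interference account of the 2x2
# object-relative-clause design: noun phrases become feature vectors,
# form overlap between similarly structured NPs causes feature
# overwriting at encoding, and retrieval of the relative-clause head
# (NP2) is scored by Luce sampling plus redintegration success.

#' Encode a noun phrase as a feature vector
#'
#' The encoding is deliberately schematic: `base_form_features` shared
#' syntactic/form tokens (identical across all NPs), one head-noun token
#' unique to the NP, and `features_per_modifier` unique semantic tokens
#' per modifier word.  A complex NP (2 modifiers) therefore differs from
#' its simple counterpart only by appended unique tokens, so a
#' non-target's elaboration is invisible to a shorter probe (candidate
#' features beyond the probe's length are ignored).
#'
#' @param id Character scalar naming the NP (e.g. `"np1"`); used to make
#'   head and modifier tokens unique.
#' @param n_modifiers Number of modifying words (0 = simple, 2 = complex).
#' @param base_form_features Number of shared form tokens (default 2).
#' @param features_per_modifier Unique semantic tokens contributed by
#'   each modifier word (default 1).
#' @return A character feature vector with attributes `form_slots`
#'   (positions of the shared form tokens), `form_class` (the NP's
#'   structural form profile, here its modifier count) and `np_id`.
#' @examples
#' encode_np("np2", n_modifiers = 2)
#' @export
encode_np <- function(id, n_modifiers = 0, base_form_features = 2,
                      features_per_modifier = 1) {
  stopifnot(n_modifiers >= 0, base_form_features >= 0,
            features_per_modifier >= 0)
  form <- if (base_form_features > 0) sprintf("form%d", seq_len(base_form_features)) else character(0)
  head_tok <- paste0("head_", id)
  mods <- if (n_modifiers * features_per_modifier > 0) {
    sprintf("sem_%s_%d", id, seq_len(n_modifiers * features_per_modifier))
  } else character(0)
  structure(c(form, head_tok, mods),
            form_slots = seq_along(form),
            form_class = n_modifiers,
            np_id = id)
}

#' The four-condition object-relative design
#'
#' Builds the NP triples (matrix subject NP1, matrix object / retrieval
#' target NP2, relative-clause subject NP3) for the 2x2 complexity
#' design.  NP3 is always simple; NP1 and NP2 each carry 0 or 2
#' modifiers.
#'
#' @inheritParams encode_np
#' @return A named list of four conditions
#'   (`simple_simple`, `complex_simple`, `simple_complex`,
#'   `complex_complex`; NP1 level first), each a list of encoded
#'   `np1`, `np2`, `np3`.
#' @export
exp1_design <- function(base_form_features = 2, features_per_modifier = 1) {
  levels <- c(simple = 0, complex = 2)
  out <- list()
  for (l1 in names(levels)) {
    for (l2 in names(levels)) {
      cond <- paste(l1, l2, sep = "_")
      out[[cond]] <- list(
        np1 = encode_np("np1", levels[[l1]], base_form_features, features_per_modifier),
        np2 = encode_np("np2", levels[[l2]], base_form_features, features_per_modifier),
        np3 = encode_np("np3", 0, base_form_features, features_per_modifier)
      )
    }
  }
  out
}

# At-risk form slots of each trace: a form feature is exposed to
# overwriting once per *other* NP with the same structural form profile
# ("matching in form"); each exposure is an independent Bernoulli(p)
# overwriting event.
.risk_table <- function(traces) {
  classes <- vapply(traces, function(tr) attr(tr, "form_class"), numeric(1))
  out <- NULL
  for (i in seq_along(traces)) {
    k <- sum(classes[-i] == classes[i])
    slots <- attr(traces[[i]], "form_slots")
    if (k > 0 && length(slots) > 0) {
      out <- rbind(out, data.frame(trace = i, slot = slots, k = k))
    }
  }
  out
}

#' Apply encoding interference (feature overwriting) to a trace set
#'
#' For each pair of traces with matching form profile (same modifier
#' count), every shared form feature is overwritten independently with
#' probability `overwrite_probability`; an overwritten slot is replaced
#' by the degraded token `"?"`.  Unique semantic and head tokens are
#' never overwritten.  A form feature shared with `k` form-matched
#' neighbours is therefore lost with probability `1 - (1 - p)^k`.
#'
#' @param traces List of encoded NPs from [encode_np()].
#' @param overwrite_probability Per-pair, per-feature overwriting
#'   probability in \[0, 1\].
#' @param seed Optional integer; if supplied, `set.seed(seed)` is called
#'   first so identical seeds give identical degraded traces.
#' @return The list of traces with overwritten slots set to `"?"`
#'   (attributes preserved).
#' @export
apply_encoding_interference <- function(traces, overwrite_probability,
                                        seed = NULL) {
  if (!is.numeric(overwrite_probability) || length(overwrite_probability) != 1L ||
      is.na(overwrite_probability) ||
      overwrite_probability < 0 || overwrite_probability > 1) {
    stop("`overwrite_probability` must be a single value in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  risk <- .risk_table(traces)
  if (is.null(risk) || overwrite_probability == 0) return(traces)
  lost <- stats::rbinom(nrow(risk), risk$k, overwrite_probability) > 0
  for (r in which(lost)) {
    tr <- traces[[risk$trace[r]]]
    tr[risk$slot[r]] <- WILDCARD
    attributes(tr) <- attributes(traces[[risk$trace[r]]])
    traces[[risk$trace[r]]] <- tr
  }
  traces
}

# Luce sampling probability of the target plus target intactness, given
# (possibly degraded) traces.  Probe = degraded target trace; its "?"
# slots follow the configured wildcard policy.  No input validation:
# internal hot path.
.condition_outcome <- function(traces, target_index = 2L,
                               wildcard = "mismatch") {
  probe <- as.character(traces[[target_index]])
  keep <- if (wildcard == "exclude") probe != WILDCARD else rep(TRUE, length(probe))
  p <- probe[keep]
  n_compared <- length(p)
  sims <- vapply(traces, function(tr) {
    cand <- as.character(tr)[seq_along(probe)][keep]
    ok <- !is.na(cand) & cand == p & p != WILDCARD & cand != WILDCARD
    exp(-sum(!ok) / n_compared)
  }, numeric(1))
  samp <- unname(sims[target_index] / sum(sims))
  intact <- mean(as.character(traces[[target_index]]) != WILDCARD)
  c(sampling = samp, intact = intact, retrieval = samp * intact)
}

#' Predict per-condition target retrieval for the 2x2 design
#'
#' For each condition the target trace (NP2), degraded by encoding
#' interference, serves as the retrieval probe against the degraded
#' NP1/NP2/NP3 candidate set.  Three quantities are reported:
#' the Luce `sampling_probability` of the target, the expected
#' `intact_proportion` of target features, and their product, the
#' `retrieval_probability` (a sampled trace must still be redintegrated,
#' which fails in proportion to its lost features).
#'
#' With interference off the sampling probability is exactly invariant
#' to NP1's complexity (a non-target's extra features lie beyond the
#' probe and are ignored).  With interference on, NP1 elaboration breaks
#' the form match with a simple NP2 and so protects the target trace.
#'
#' @param design Conditions from [exp1_design()].
#' @param overwrite_probability Per-pair, per-feature overwriting
#'   probability (default 0.3).
#' @param method `"exact"` enumerates all loss patterns (deterministic);
#'   `"mc"` averages `reps` Monte-Carlo interference replicates and
#'   reports a Monte-Carlo standard error.
#' @param reps Monte-Carlo replicates (default 10000; `method = "mc"`).
#' @param wildcard Probe `"?"` policy; see [count_mismatches()].
#' @param seed Optional seed for `method = "mc"`.
#' @return Data frame with one row per condition: `condition`, `np1`,
#'   `np2`, `sampling_probability`, `intact_proportion`,
#'   `retrieval_probability`, `mc_se` (NA for `"exact"`).
#' @examples
#' predict_conditions(method = "exact")
#' @export
predict_conditions <- function(design = exp1_design(),
                               overwrite_probability = 0.3,
                               method = c("exact", "mc"),
                               reps = 10000,
                               wildcard = c("mismatch", "exclude"),
                               seed = NULL) {
  method <- match.arg(method)
  wildcard <- match.arg(wildcard)
  if (overwrite_probability < 0 || overwrite_probability > 1) {
    stop("`overwrite_probability` must be in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(names(design), function(cond) {
    traces <- design[[cond]][c("np1", "np2", "np3")]
    if (method == "exact") {
      est <- .exact_outcome(traces, overwrite_probability, wildcard)
      mc_se <- NA_real_
    } else {
      draws <- matrix(NA_real_, nrow = reps, ncol = 3)
      for (r in seq_len(reps)) {
        deg <- apply_encoding_interference(traces, overwrite_probability)
        draws[r, ] <- .condition_outcome(deg, 2L, wildcard)
      }
      est <- colMeans(draws)
      names(est) <- c("sampling", "intact", "retrieval")
      mc_se <- stats::sd(draws[, 3]) / sqrt(reps)
    }
    lv <- strsplit(cond, "_")[[1]]
    data.frame(condition = cond, np1 = lv[1], np2 = lv[2],
               sampling_probability = est[["sampling"]],
               intact_proportion = est[["intact"]],
               retrieval_probability = est[["retrieval"]],
               mc_se = mc_se)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Exact expectation over loss patterns: at-risk slots are few (two form
# features per NP at the defaults), so the joint loss distribution is
# enumerable.
.exact_outcome <- function(traces, p, wildcard) {
  risk <- .risk_table(traces)
  if (is.null(risk) || p == 0) {
    return(.condition_outcome(traces, 2L, wildcard))
  }
  q <- 1 - (1 - p)^risk$k
  patterns <- expand.grid(rep(list(c(0L, 1L)), nrow(risk)))
  acc <- c(sampling = 0, intact = 0, retrieval = 0)
  for (r in seq_len(nrow(patterns))) {
    z <- as.integer(patterns[r, ])
    w <- prod(ifelse(z == 1L, q, 1 - q))
    deg <- traces
    for (j in which(z == 1L)) {
      tr <- deg[[risk$trace[j]]]
      tr[risk$slot[j]] <- WILDCARD
      attributes(tr) <- attributes(deg[[risk$trace[j]]])
      deg[[risk$trace[j]]] <- tr
    }
    acc <- acc + w * .condition_outcome(deg, 2L, wildcard)
  }
  acc
}
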