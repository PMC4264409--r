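# Synthetic word-by-word self-paced-reading data with the statistical
# structure of the two factorial experiments: Latin-square condition
# assignment, word-length and log-list-position effects, crossed random
# effects, encoding costs at manipulated words, and a retrieval cost at
# the relative-clause verb linked to the memory model.

#' Generator parameters for synthetic self-paced reading data
#'
#' Defaults reflect the study conditions: Experiment 1 ran 52
#' participants, 28 critical object-relative items and 70 fillers with a
#' 2x2 NP1/NP2-complexity design; Experiment 2 ran 44 participants, 32
#' items and 60 fillers with a 2x2 noun-color/verb-color design.  All
#' reading times are generated on the log-ms scale and exponentiated.
#'
#' @param experiment 1 or 2.
#' @param n_participants,n_items,n_fillers Design sizes.
#' @param mu_log_rt Grand mean log reading time (log ms; default 5.9,
#'   about 365 ms).
#' @param beta_length Fixed effect of word length, per character.
#' @param beta_logpos Fixed effect of log list position (practice;
#'   negative = speed-up over the session).
#' @param sd_participant,sd_item SDs of by-participant and by-item
#'   random intercepts.
#' @param sd_part_slope,sd_item_slope SDs of by-participant and by-item
#'   random slopes for each sum-coded condition effect (applied at the
#'   retrieval region and its spillover).
#' @param sd_resid Residual SD of log RT.
#' @param encoding_cost Log-RT cost per additional target feature,
#'   applied at the head of a modified NP (experiment 1).
#' @param kappa Retrieval-cost coefficient: the relative-clause verb's
#'   log RT carries `kappa * (-log p)` where `p` is the condition's
#'   target retrieval probability from [predict_conditions()]
#'   (experiment 1).
#' @param carryover Spillover fraction: the word after a manipulated
#'   word inherits this fraction of the preceding word's realized
#'   deviation (its condition cost, condition slopes and trial noise),
#'   mimicking the carry-over of a delayed key press.
#' @param overwrite_probability Encoding-interference overwriting
#'   probability fed to [predict_conditions()] (experiment 1).
#' @param base_form_features,features_per_modifier Feature-granularity
#'   settings passed to [exp1_design()].
#' @param noun_color_cost,verb_color_cost Log-RT encoding cost of an
#'   incongruently colored (green) noun / verb at that word
#'   (experiment 2).
#' @param reinstatement Additional log-RT shift at the verb when both
#'   noun and verb are green (default 0: color congruence confers no
#'   retrieval benefit, the empirical finding).
#' @param retrieval_at Region carrying the full retrieval cost
#'   (experiment 1): `"RC_verb"` (default) or `"RC_verb-1"`.  The
#'   latter generates data whose verb-region effect is pure spillover
#'   from the preceding word, for covariate checks.
#' @param contamination Fraction of words drawn from a heavy slow tail
#'   (> 5000 ms) to exercise trimming.
#' @param accuracy Marginal probability that a comprehension question is
#'   answered correctly (default 0.84, the observed overall accuracy).
#' @param filler_length Words per filler sentence.
#' @return A validated list of class `"spr_params"`.
#' @export
spr_params <- function(experiment = 1,
                       n_participants = if (experiment == 1) 52 else 44,
                       n_items = if (experiment == 1) 28 else 32,
                       n_fillers = if (experiment == 1) 70 else 60,
                       mu_log_rt = 5.9,
                       beta_length = 0.025,
                       beta_logpos = -0.04,
                       sd_participant = 0.12,
                       sd_item = 0.05,
                       sd_part_slope = 0.015,
                       sd_item_slope = 0.015,
                       sd_resid = 0.25,
                       encoding_cost = 0.03,
                       kappa = 0.22,
                       carryover = 0.9,
                       overwrite_probability = 0.3,
                       base_form_features = 2,
                       features_per_modifier = 1,
                       noun_color_cost = 0.08,
                       verb_color_cost = 0.065,
                       reinstatement = 0,
                       retrieval_at = "RC_verb",
                       contamination = 0.001,
                       accuracy = 0.84,
                       filler_length = 8) {
  p <- as.list(environment())
  if (!experiment %in% c(1, 2)) stop("`experiment` must be 1 or 2")
  counts <- c(p$n_participants, p$n_items, p$n_fillers, p$filler_length)
  if (any(counts < 1)) stop("counts must be >= 1")
  sds <- c(p$sd_participant, p$sd_item, p$sd_part_slope, p$sd_item_slope, p$sd_resid)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (p$carryover < 0 || p$carryover > 1) stop("`carryover` must be in [0, 1]")
  if (!p$retrieval_at %in% c("RC_verb", "RC_verb-1")) {
    stop("`retrieval_at` must be \"RC_verb\" or \"RC_verb-1\"")
  }
  if (p$contamination < 0 || p$contamination > 1) stop("`contamination` must be in [0, 1]")
  if (p$accuracy < 0 || p$accuracy > 1) stop("`accuracy` must be in [0, 1]")
  if (p$overwrite_probability < 0 || p$overwrite_probability > 1) {
    stop("`overwrite_probability` must be in [0, 1]")
  }
  structure(p, class = "spr_params")
}

.rand_word <- function(n, min_len = 4, max_len = 9) {
  lens <- sample(min_len:max_len, n, replace = TRUE)
  vapply(lens, function(L) paste(sample(letters, L, replace = TRUE), collapse = ""),
         character(1))
}

.latin_condition <- function(participant, item, conditions) {
  list_id <- (participant - 1L) %% length(conditions)
  conditions[((item - 1L + list_id) %% length(conditions)) + 1L]
}

# Word-level plan for one critical item in one condition of the
# object-relative template:
#   The (m m) NP1 verb the (m m) NP2 who a NP3 post1 post2 rc_verb
#   spill1 spill2 spill3
# `cost` carries condition-specific deterministic log-RT offsets at the
# word (encoding costs, retrieval costs); `slope_weight` marks the rows
# that receive condition random slopes; `carry` is the fraction of the
# *previous* word's realized deviation (cost + slopes + noise) the word
# inherits.
.exp1_item_plan <- function(lex, cond, params, retr_cost) {
  lv <- strsplit(cond, "_")[[1]]
  np1_cx <- lv[1] == "complex"; np2_cx <- lv[2] == "complex"
  extra <- 2 * params$features_per_modifier
  kr <- params$kappa * retr_cost
  at_verb <- params$retrieval_at == "RC_verb"
  w <- character(0); reg <- character(0); cost <- numeric(0)
  sw <- numeric(0); cy <- numeric(0)
  add <- function(word, region = "other", off = 0, weight = 0, carry = 0) {
    w <<- c(w, word); reg <<- c(reg, region); cost <<- c(cost, off)
    sw <<- c(sw, weight); cy <<- c(cy, carry)
  }
  add("the")
  if (np1_cx) { add(lex$np1_mods[1]); add(lex$np1_mods[2]) }
  add(lex$np1_head, off = if (np1_cx) params$encoding_cost * extra else 0)
  add(lex$main_verb)
  add("the")
  if (np2_cx) { add(lex$np2_mods[1]); add(lex$np2_mods[2]) }
  add(lex$np2_head, "NP2_head", if (np2_cx) params$encoding_cost * extra else 0)
  add("who")
  add("a")
  add(lex$np3_head, "NP3_head")
  add(lex$post1, "NP3_head+1")
  add(lex$post2, "RC_verb-1", off = if (at_verb) 0 else kr,
      weight = if (at_verb) 0 else 1)
  add(lex$rc_verb, "RC_verb", off = if (at_verb) kr else 0,
      weight = if (at_verb) 1 else 0,
      carry = if (at_verb) 0 else params$carryover)
  add(lex$spill[1], "RC_verb+1", carry = if (at_verb) params$carryover else 0)
  add(lex$spill[2]); add(lex$spill[3])
  data.frame(word = w, region = reg, cost = cost,
             word_index = seq_along(w), slope_weight = sw, carry = cy)
}

.exp2_item_plan <- function(lex, cond, params) {
  lv <- strsplit(cond, "_")[[1]]
  noun_green <- lv[1] == "green"; verb_green <- lv[2] == "green"
  verb_cost <- (if (verb_green) params$verb_color_cost else 0) +
    (if (noun_green && verb_green) params$reinstatement else 0)
  w <- c("the", lex$np1_head, lex$main_verb, "the", lex$np2_head,
         "who", "the", lex$np3_head, lex$post1, lex$post2,
         lex$rc_verb, lex$spill[1], lex$spill[2], lex$spill[3])
  reg <- c("other", "other", "other", "other", "NP2_head",
           "other", "other", "NP3_head", "NP3_head+1", "RC_verb-1",
           "RC_verb", "RC_verb+1", "other", "other")
  cost <- numeric(length(w))
  cost[reg == "NP2_head"] <- if (noun_green) params$noun_color_cost else 0
  cost[reg == "RC_verb"] <- verb_cost
  data.frame(word = w, region = reg, cost = cost,
             word_index = seq_along(w),
             slope_weight = ifelse(reg == "RC_verb", 1, 0),
             carry = ifelse(reg == "RC_verb+1", params$carryover, 0))
}

.item_lexicon <- function() {
  list(np1_head = .rand_word(1, 5, 10), np1_mods = .rand_word(2, 4, 9),
       main_verb = .rand_word(1, 5, 10), np2_head = .rand_word(1, 5, 10),
       np2_mods = .rand_word(2, 4, 9), np3_head = .rand_word(1, 5, 10),
       post1 = .rand_word(1, 2, 5), post2 = .rand_word(1, 3, 8),
       rc_verb = .rand_word(1, 5, 10), spill = .rand_word(3, 2, 8))
}

.generate_spr <- function(params, seed, conditions, plan_fun) {
  set.seed(seed)
  np <- params$n_participants; ni <- params$n_items; nf <- params$n_fillers
  n_trials <- ni + nf

  # per-item word plans for every condition
  plans <- list()
  for (i in seq_len(ni)) {
    lex <- .item_lexicon()
    for (cond in conditions) {
      plans[[paste(i, cond)]] <- plan_fun(lex, cond, i)
    }
  }
  for (f in seq_len(nf)) {
    plans[[paste(ni + f, "filler")]] <- data.frame(
      word = .rand_word(params$filler_length, 2, 9),
      region = "other", cost = 0,
      word_index = seq_len(params$filler_length), slope_weight = 0,
      carry = 0)
  }

  b_part <- stats::rnorm(np, 0, params$sd_participant)
  b_item <- stats::rnorm(n_trials, 0, params$sd_item)
  u_slope <- matrix(stats::rnorm(np * 3, 0, params$sd_part_slope), np, 3)
  w_slope <- matrix(stats::rnorm(n_trials * 3, 0, params$sd_item_slope), n_trials, 3)

  out <- vector("list", np)
  for (p in seq_len(np)) {
    cond_of_item <- vapply(seq_len(ni), function(i) .latin_condition(p, i, conditions),
                           character(1))
    trial_item <- c(seq_len(ni), ni + seq_len(nf))
    trial_cond <- c(cond_of_item, rep("filler", nf))
    ord <- sample.int(n_trials)
    trial_item <- trial_item[ord]; trial_cond <- trial_cond[ord]
    keys <- paste(trial_item, trial_cond)
    nw <- vapply(plans[keys], nrow, integer(1))
    plan <- do.call(rbind, plans[keys])
    item <- rep(trial_item, nw)
    cond <- rep(trial_cond, nw)
    pos <- rep(seq_len(n_trials), nw)
    correct <- rep(stats::rbinom(n_trials, 1, params$accuracy), nw)
    xs <- .condition_contrasts(cond, conditions)
    slope <- plan$slope_weight *
      (u_slope[p, 1] * xs[, 1] + u_slope[p, 2] * xs[, 2] + u_slope[p, 3] * xs[, 3] +
       w_slope[cbind(item, 1)] * xs[, 1] + w_slope[cbind(item, 2)] * xs[, 2] +
       w_slope[cbind(item, 3)] * xs[, 3])
    eps <- stats::rnorm(length(pos), 0, params$sd_resid)
    # trial-internal deviation; spillover words inherit a fraction of
    # the previous word's realized deviation
    dev <- plan$cost + slope + eps
    ci <- which(plan$carry > 0)
    dev[ci] <- dev[ci] + plan$carry[ci] * dev[ci - 1L]
    y <- params$mu_log_rt +
      params$beta_length * nchar(plan$word) +
      params$beta_logpos * log(pos) +
      b_part[p] + b_item[item] + dev
    rt <- exp(y)
    contam <- stats::runif(length(rt)) < params$contamination
    if (any(contam)) {
      rt[contam] <- exp(stats::runif(sum(contam), log(5500), log(20000)))
    }
    out[[p]] <- data.frame(
      participant = p, item = item, condition = cond,
      is_filler = cond == "filler", list_position = pos,
      word_index = plan$word_index, word = plan$word,
      word_length = nchar(plan$word), region = plan$region,
      rt = round(rt, 1), correct = correct)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Sum-coded contrasts (level-2 = +1) for the three condition effects at
# generation time; fillers get 0.
.condition_contrasts <- function(cond, conditions) {
  lv <- strsplit(conditions, "_")
  f1 <- vapply(lv, `[`, character(1), 1); f2 <- vapply(lv, `[`, character(1), 2)
  pos1 <- setdiff(unique(f1), c("simple", "white"))  # complex / green = +1
  pos2 <- setdiff(unique(f2), c("simple", "white"))
  cl <- strsplit(cond, "_")
  x1 <- ifelse(cond == "filler", 0,
               ifelse(vapply(cl, `[`, character(1), 1) == pos1, 1, -1))
  x2 <- ifelse(cond == "filler", 0,
               ifelse(vapply(cl, `[`, character(1), 2) == pos2, 1, -1))
  cbind(x1, x2, x1 * x2)
}

#' Generate a synthetic Experiment-1 dataset (NP complexity design)
#'
#' Word-by-word reading times for the 2x2 object-relative design: NP1
#' and NP2 each simple (0 modifiers) or complex (2 modifiers), assigned
#' by Latin square so each participant sees each item in exactly one
#' condition.  Log RT is the sum of the grand mean, word-length and
#' log-list-position effects, crossed random intercepts, condition
#' random slopes at the retrieval region, an encoding cost at modified
#' NP heads, a retrieval cost `kappa * (-log p_target)` at the
#' relative-clause verb (with spillover), and Gaussian noise.  Target
#' retrieval probabilities come from [predict_conditions()] with
#' `method = "exact"`.
#'
#' @param params An [spr_params()] object (`experiment = 1`).
#' @param seed Integer seed; identical `params` + `seed` give a
#'   byte-identical dataset.
#' @return A long-format data frame with columns `participant`, `item`,
#'   `condition`, `is_filler`, `list_position`, `word_index`, `word`,
#'   `word_length`, `region`, `rt` (ms), `correct`.
#' @examples
#' d <- generate_exp1(spr_params(1, n_participants = 4, n_items = 4,
#'                               n_fillers = 4), seed = 1)
#' head(d)
#' @export
generate_exp1 <- function(params = spr_params(1), seed = 1) {
  stopifnot(inherits(params, "spr_params"))
  if (params$experiment != 1) stop("`params` must have experiment = 1")
  conditions <- c("simple_simple", "complex_simple", "simple_complex",
                  "complex_complex")
  pc <- predict_conditions(
    design = exp1_design(params$base_form_features, params$features_per_modifier),
    overwrite_probability = params$overwrite_probability, method = "exact")
  retr <- -log(pc$retrieval_probability)
  names(retr) <- pc$condition
  # center the retrieval cost so kappa shifts condition contrasts, not
  # the region's grand mean
  retr <- retr - mean(retr)
  plan_fun <- function(lex, cond, item) .exp1_item_plan(lex, cond, params, retr[[cond]])
  .generate_spr(params, seed, conditions, plan_fun)
}

#' Generate a synthetic Experiment-2 dataset (color congruence design)
#'
#' 2x2 noun-color by verb-color design: the object head noun and the
#' relative-clause verb each appear congruent (white) or isolated
#' (green).  A green word carries an encoding cost at that word; by
#' default there is no retrieval benefit of noun color at the verb
#' (`reinstatement = 0`), matching the empirical absence of isolation
#' effects at retrieval.
#'
#' @param params An [spr_params()] object (`experiment = 2`).
#' @param seed Integer seed.
#' @return A long-format data frame; see [generate_exp1()].
#' @export
generate_exp2 <- function(params = spr_params(2), seed = 1) {
  stopifnot(inherits(params, "spr_params"))
  if (params$experiment != 2) stop("`params` must have experiment = 2")
  conditions <- c("white_white", "green_white", "white_green", "green_green")
  plan_fun <- function(lex, cond, item) .exp2_item_plan(lex, cond, params)
  .generate_spr(params, seed, conditions, plan_fun)
}
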