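# Shared helpers: an independent brute-force comparison oracle and
# scaled-down generator / sampler settings for simulation tests.

# Slot-by-slot comparison written as an explicit loop, independent of
# the package's vectorized implementation.
oracle_mismatches <- function(probe, candidate, wildcard = "mismatch") {
  n <- 0L
  for (i in seq_along(probe)) {
    if (wildcard == "exclude" && probe[i] == "?") next
    hit <- FALSE
    if (i <= length(candidate)) {
      hit <- probe[i] == candidate[i] && probe[i] != "?" && candidate[i] != "?"
    }
    if (!hit) n <- n + 1L
  }
  n
}

small_exp1 <- function(...) {
  spr_params(1, n_participants = 8, n_items = 12, n_fillers = 10,
             filler_length = 6, ...)
}

prep <- function(d, ...) residualize(trim_rts(d)$data, ...)

fit_quick <- function(data, region, seed = 1, iter = 1200, warmup = 400, ...) {
  suppressWarnings(fit_region(data, region, chains = 2, iter = iter,
                              warmup = warmup, seed = seed, ...))
}

p_of <- function(fit, factor) fit$p_beta_lt_0[fit$factor == factor]

# drop posterior-draw attributes so summaries can be compared directly
strip_fit <- function(f) {
  attributes(f) <- attributes(f)[c("names", "row.names")]
  class(f) <- "data.frame"
  f
}
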