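# Distinctiveness / competitor-load sweeps over abstract retrieval
# configurations: a target sharing m features with every competitor and
# carrying u contextually unique features.

#' Build an abstract sweep scenario
#'
#' Constructs a retrieval scenario in which the probe equals the target
#' trace and consists of `m` features shared with every competitor plus
#' `u` features unique to the target.  Each of the `n_competitors`
#' competitor traces matches the probe on exactly the `m` shared
#' positions and mismatches everywhere else.
#'
#' @param m Number of probe features matching each competitor (>= 0).
#' @param u Number of contextually unique target features (>= 0);
#'   `m + u >= 1`.
#' @param n_competitors Number of competitor traces (>= 1).
#' @return A [retrieval_scenario()] with the target first.
#' @examples
#' sc <- build_sweep_scenario(m = 2, u = 3, n_competitors = 2)
#' sampling_probabilities(sc)$target_probability
#' @export
build_sweep_scenario <- function(m, u, n_competitors) {
  if (m < 0 || u < 0 || m + u < 1 || n_competitors < 1) {
    stop("need m >= 0, u >= 0, m + u >= 1 and n_competitors >= 1")
  }
  shared <- if (m > 0) sprintf("s%d", seq_len(m)) else character(0)
  unique_feats <- if (u > 0) sprintf("t%d", seq_len(u)) else character(0)
  target <- c(shared, unique_feats)
  competitors <- lapply(seq_len(n_competitors), function(j) {
    c(shared, if (u > 0) sprintf("c%d_%d", j, seq_len(u)) else character(0))
  })
  retrieval_scenario(probe = target,
                     traces = c(list(target), competitors),
                     target_index = 1L)
}

sweep_point <- function(m, u, n) {
  sampling_probabilities(build_sweep_scenario(m, u, n))$target_probability
}

#' Distinctiveness sweep: unique target features vs. sampling probability
#'
#' For every combination of matching features `m` and unique target
#' features `u` (at fixed competitor count), computes the deterministic
#' Luce sampling probability of the target.  As `u` grows the target's
#' advantage shows diminishing returns, asymptoting at
#' `1 / (1 + n * exp(-1))`.
#'
#' @param m Integer vector of matching-feature counts (default `2:10`).
#' @param u Integer vector of unique-feature counts (default `0:20`).
#' @param n_competitors Number of competitors (default 2).
#' @return A data frame with columns `m`, `u`, `n_competitors`,
#'   `target_probability`.
#' @examples
#' head(distinctiveness_sweep(m = 2, u = 0:5))
#' @export
distinctiveness_sweep <- function(m = 2:10, u = 0:20, n_competitors = 2) {
  grid <- expand.grid(m = m, u = u, n_competitors = n_competitors,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$m + grid$u >= 1, , drop = FALSE]
  grid$target_probability <- mapply(sweep_point, grid$m, grid$u, grid$n_competitors)
  rownames(grid) <- NULL
  grid
}

#' Competitor sweep: competitor count vs. sampling probability
#'
#' Same contract as [distinctiveness_sweep()] but varying the number of
#' competitors.  With `u = 0` all candidates are equally similar and the
#' target probability is the closed form `1 / (n + 1)`.
#'
#' @param m Matching-feature count (default 2).
#' @param u Integer vector of unique-feature counts (default `0:20`).
#' @param n_competitors Integer vector of competitor counts (default `1:10`).
#' @return A data frame with columns `m`, `u`, `n_competitors`,
#'   `target_probability`.
#' @export
competitor_sweep <- function(m = 2, u = 0:20, n_competitors = 1:10) {
  distinctiveness_sweep(m = m, u = u, n_competitors = n_competitors)
}
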