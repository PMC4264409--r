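test_that("mismatch counting is positional and probe-asymmetric", {
  probe5 <- c("C", "C", "2", "3", "1")
  probe8 <- c("C", "C", "2", "3", "1", "Q", "R", "N")
  cand <- c("C", "C", "1", "2", "3")

  expect_identical(count_mismatches(probe5, cand), 3L)
  expect_identical(count_mismatches(probe5, probe5), 0L)
  # probe slots without a counterpart count as mismatches
  expect_identical(count_mismatches(probe8, cand), 6L)
  # candidate surplus features are ignored
  expect_identical(count_mismatches(probe5, c(cand, "L", "M")), 3L)

  expect_equal(feature_distance(probe5, cand), 0.6)
  expect_equal(feature_distance(probe5, probe5), 0)
  expect_equal(feature_distance(probe8, cand), 0.75)

  expect_equal(round(feature_similarity(probe5, cand), 2), 0.55)
  expect_equal(feature_similarity(probe5, probe5), 1.0)
  expect_equal(round(feature_similarity(probe8, cand), 2), 0.47)
})

test_that("degraded slots follow the configured wildcard policy", {
  probe <- c("C", "?", "2")
  cand <- c("C", "C", "2")
  # default: a blurry slot supports no match
  expect_identical(count_mismatches(probe, cand), 1L)
  expect_equal(feature_distance(probe, cand), 1 / 3)
  # alternative: drop the slot from probe and denominator
  expect_identical(count_mismatches(probe, cand, wildcard = "exclude"), 0L)
  expect_equal(feature_distance(probe, cand, wildcard = "exclude"), 0)
  # a lost candidate feature matches nothing, not even another "?"
  expect_identical(count_mismatches(c("C", "?"), c("C", "?")), 1L)
  expect_identical(count_mismatches("C", "?"), 1L)

  expect_error(feature_distance(c("?", "?"), cand, wildcard = "exclude"),
               "no compared features")
  expect_error(count_mismatches(character(0), cand), "at least one feature")
  expect_error(feature_vector(c("C", "?")), "only permitted in probes")
  expect_silent(feature_vector(c("C", "?"), probe = TRUE))
})

test_that("distance matches a brute-force oracle over a small vocabulary", {
  alphabet <- c("a", "b", "?")
  vecs <- unlist(lapply(1:3, function(L) {
    apply(expand.grid(rep(list(alphabet), L)), 1,
          function(r) list(as.character(r)))
  }), recursive = FALSE)
  vecs <- lapply(vecs, `[[`, 1)
  set.seed(101)
  pick <- function() vecs[[sample.int(length(vecs), 1)]]
  for (rep in 1:400) {
    p <- pick(); cand <- pick()
    for (w in c("mismatch", "exclude")) {
      expect_identical(count_mismatches(p, cand, wildcard = w),
                       oracle_mismatches(p, cand, w),
                       info = paste(w, paste(p, collapse = ""), "|",
                                    paste(cand, collapse = "")))
    }
  }
  # longer random pairs over a 3-symbol alphabet
  for (rep in 1:200) {
    p <- sample(c("x", "y", "z"), sample(4:6, 1), replace = TRUE)
    cand <- sample(c("x", "y", "z"), sample(1:6, 1), replace = TRUE)
    expect_identical(count_mismatches(p, cand), oracle_mismatches(p, cand))
  }
})

test_that("sampling probabilities normalize and respect bounds", {
  set.seed(7)
  for (rep in 1:50) {
    n_tr <- sample(1:6, 1)
    probe <- sample(letters[1:4], sample(2:6, 1), replace = TRUE)
    traces <- replicate(n_tr,
                        sample(letters[1:4], sample(1:7, 1), replace = TRUE),
                        simplify = FALSE)
    sc <- retrieval_scenario(probe, traces, sample(n_tr, 1))
    res <- sampling_probabilities(sc)
    expect_lt(abs(sum(res$probability) - 1), 1e-12)
    expect_true(all(res$similarity >= exp(-1) - 1e-15))
    expect_true(all(res$similarity <= 1 + 1e-15))
  }
  solo <- retrieval_scenario(c("a", "b"), list(c("q", "r")), 1)
  expect_equal(sampling_probabilities(solo)$target_probability, 1.0)
})

test_that("features a competitor carries beyond the probe are inert", {
  probe <- c("C", "X", "1", "2", "3")
  base <- retrieval_scenario(probe, list(probe, c("C", "X", "4", "5", "6")), 1)
  extended <- retrieval_scenario(
    probe, list(probe, c("C", "X", "4", "5", "6", "L", "M")), 1)
  expect_identical(sampling_probabilities(base)$target_probability,
                   sampling_probabilities(extended)$target_probability)

  set.seed(11)
  for (rep in 1:20) {
    tr <- replicate(3, sample(letters[1:3], 4, replace = TRUE), simplify = FALSE)
    p0 <- sampling_probabilities(retrieval_scenario(tr[[1]], tr, 1))
    tr2 <- tr
    tr2[[3]] <- c(tr2[[3]], sample(letters, sample(1:4, 1), replace = TRUE))
    p1 <- sampling_probabilities(retrieval_scenario(tr[[1]], tr2, 1))
    expect_identical(p0$target_probability, p1$target_probability)
  }
})

test_that("scenario construction rejects invalid input", {
  expect_error(retrieval_scenario(c("a"), list(), 1), "non-empty")
  expect_error(retrieval_scenario(c("a"), list(c("a")), 2), "index")
  expect_error(retrieval_scenario(c("a", ""), list(c("a")), 1), "empty")
})
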