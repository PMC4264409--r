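test_that("experiment-1 datasets have the full design structure", {
  d <- generate_exp1(spr_params(1), seed = 11)

  expect_named(d, c("participant", "item", "condition", "is_filler",
                    "list_position", "word_index", "word", "word_length",
                    "region", "rt", "correct"))
  expect_true(all(d$rt > 0))

  crit <- d[!d$is_filler, ]
  trials <- unique(crit[, c("participant", "item", "condition")])
  expect_equal(nrow(trials), 52 * 28)

  # each participant sees each item in exactly one condition
  expect_equal(nrow(unique(trials[, c("participant", "item")])), 52 * 28)

  # Latin-square balance: every condition of every item seen by
  # n_participants / 4 participants (+- 1)
  tab <- table(trials$item, trials$condition)
  expect_true(all(abs(tab - 13) <= 1))

  # each critical region appears exactly once per critical trial
  for (reg in c("NP2_head", "NP3_head", "NP3_head+1", "RC_verb-1",
                "RC_verb", "RC_verb+1")) {
    n_reg <- tapply(crit$region == reg,
                    paste(crit$participant, crit$item), sum)
    expect_true(all(n_reg == 1), info = reg)
  }

  # word length matches the word strings
  expect_identical(d$word_length, nchar(d$word))
})

test_that("generation is seed-deterministic and the CSV round trip is lossless", {
  params <- small_exp1()
  d1 <- generate_exp1(params, seed = 3)
  d2 <- generate_exp1(params, seed = 3)
  expect_identical(d1, d2)
  expect_false(identical(d1, generate_exp1(params, seed = 4)))

  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_spr(d1, f1)
  write_spr(d2, f2)
  expect_identical(readLines(f1), readLines(f2))

  back <- read_spr(f1)
  expect_equal(back, d1)

  expect_error(write_spr(d1[, -10], f1), "missing column")
  lines <- readLines(f1)
  expect_error(read_spr({writeLines(lines[-1], f2); f2}), "missing column")
  lines[5] <- sub("^(([^,]*,){9})[^,]*", "\\1oops", lines[5])
  writeLines(lines, f2)
  expect_error(read_spr(f2), "line\\(s\\) 5")
})

test_that("generated effects appear at the intended regions", {
  d <- generate_exp1(spr_params(1, n_participants = 20), seed = 21)
  crit <- d[!d$is_filler, ]
  np2 <- vapply(strsplit(crit$condition, "_"), `[`, character(1), 2)

  verb <- log(crit$rt[crit$region == "RC_verb"])
  np2_verb <- np2[crit$region == "RC_verb"]
  expect_lt(mean(verb[np2_verb == "complex"]), mean(verb[np2_verb == "simple"]))

  spill <- log(crit$rt[crit$region == "RC_verb+1"])
  np2_spill <- np2[crit$region == "RC_verb+1"]
  expect_lt(mean(spill[np2_spill == "complex"]), mean(spill[np2_spill == "simple"]))

  head_rt <- log(crit$rt[crit$region == "NP2_head"])
  np2_head <- np2[crit$region == "NP2_head"]
  expect_gt(mean(head_rt[np2_head == "complex"]), mean(head_rt[np2_head == "simple"]))
})

test_that("the null generator produces no spurious condition effects", {
  params <- small_exp1(kappa = 0, encoding_cost = 0)
  rejections <- 0
  for (rep in 1:30) {
    d <- generate_exp1(params, seed = 400 + rep)
    v <- d[!d$is_filler & d$region == "RC_verb", ]
    v$np2 <- vapply(strsplit(v$condition, "_"), `[`, character(1), 2)
    by_part <- aggregate(log(rt) ~ participant + np2, data = v, FUN = mean)
    wide <- reshape(by_part, idvar = "participant", timevar = "np2",
                    direction = "wide")
    pval <- t.test(wide[["log(rt).complex"]], wide[["log(rt).simple"]],
                   paired = TRUE)$p.value
    rejections <- rejections + (pval < 0.05)
  }
  expect_lte(rejections, 6)  # Binomial(30, 0.05): P(X > 6) < 1e-3
})

test_that("residual log-RT noise is Gaussian at null settings", {
  params <- small_exp1(kappa = 0, encoding_cost = 0, sd_participant = 0,
                       sd_item = 0, sd_part_slope = 0, sd_item_slope = 0,
                       contamination = 0)
  d <- generate_exp1(params, seed = 8)
  eps <- log(d$rt) - (params$mu_log_rt + params$beta_length * d$word_length +
                        params$beta_logpos * log(d$list_position))
  expect_lt(abs(sd(eps) - params$sd_resid), 0.015)
  ks <- suppressWarnings(ks.test(eps / sd(eps), "pnorm"))
  expect_gt(ks$p.value, 0.001)
})

test_that("experiment-2 color costs arise at the colored words only", {
  d <- generate_exp2(spr_params(2), seed = 31)
  crit <- d[!d$is_filler, ]
  noun <- vapply(strsplit(crit$condition, "_"), `[`, character(1), 1)
  verb_col <- vapply(strsplit(crit$condition, "_"), `[`, character(1), 2)

  at <- function(region) crit$region == region
  # green noun slows the noun; green verb slows the verb
  expect_gt(mean(log(crit$rt[at("NP2_head") & noun == "green"])),
            mean(log(crit$rt[at("NP2_head") & noun == "white"])))
  expect_gt(mean(log(crit$rt[at("RC_verb") & verb_col == "green"])),
            mean(log(crit$rt[at("RC_verb") & verb_col == "white"])))

  # no retrieval benefit of noun color at the verb by construction
  diff_null <- mean(log(crit$rt[at("RC_verb") & noun == "green"])) -
    mean(log(crit$rt[at("RC_verb") & noun == "white"]))
  expect_lt(abs(diff_null), 0.045)

  # ... unless a reinstatement term is switched on
  d2 <- generate_exp2(spr_params(2, reinstatement = -0.2), seed = 31)
  c2 <- d2[!d2$is_filler & d2$region == "RC_verb", ]
  gg <- log(c2$rt[c2$condition == "green_green"])
  wg <- log(c2$rt[c2$condition == "white_green"])
  expect_lt(mean(gg), mean(wg) - 0.1)

  # structure: one row per critical region per trial
  for (reg in c("NP2_head", "NP3_head", "RC_verb", "RC_verb+1")) {
    n_reg <- tapply(crit$region == reg,
                    paste(crit$participant, crit$item), sum)
    expect_true(all(n_reg == 1), info = reg)
  }
})
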