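test_that("procedure specifications validate their parameters", {
  expect_error(rand_spec("rar", n = 23), "even")
  expect_error(rand_spec("pbr", n = 24, l = 3), "even")
  expect_error(rand_spec("ebc", n = 24, p = 0.5), "between")
  expect_error(rand_spec("ebc", n = 24, p = 1), "between")
  expect_error(rand_spec("ebc", n = 24), "between")
  expect_error(rand_spec("bsd", n = 24), "'m'")
  expect_error(rand_spec("cr", n = 24, p = 0.6), "not a parameter")
  expect_error(rand_spec("rpbr", n = 24, block_set = c(2, 3)), "even")
  expect_s3_class(rand_spec("chen", n = 24, p = 2/3, m = 3), "rand_spec")
})

test_that("generated sequences honour each procedure's balance law", {
  n <- 24
  imb <- function(s) t(apply(s, 1, function(r) cumsum(2L * r - 1L)))

  rar <- generate_sequences(rand_spec("rar", n = n), 500, seed = 1)
  expect_true(all(rowSums(rar) == n / 2))

  pbr <- generate_sequences(rand_spec("pbr", n = n, l = 4), 500, seed = 2)
  expect_true(all(imb(pbr)[, seq(4, n, 4)] == 0))

  for (spec in list(rand_spec("bsd", n = n, m = 3),
                    rand_spec("chen", n = n, p = 2/3, m = 3))) {
    s <- generate_sequences(spec, 10000, seed = 3)
    expect_lte(max(abs(imb(s))), 3)
  }

  ## randomized blocks: imbalance can never exceed half the largest block
  ## (the final block may be truncated at n, so exact final balance is not
  ## guaranteed)
  rpbr <- generate_sequences(rand_spec("rpbr", n = n, block_set = c(2, 4)), 200,
                             seed = 4)
  expect_lte(max(abs(imb(rpbr))), 2)
})

test_that("CR is a fair coin at every position and EBC follows its bias", {
  n <- 24
  cr <- generate_sequences(rand_spec("cr", n = n), 10000, seed = 5)
  freq <- colMeans(cr)
  se3 <- 3 * sqrt(0.25 / nrow(cr))
  expect_true(all(abs(freq - 0.5) < se3))

  p <- 2/3
  ebc <- generate_sequences(rand_spec("ebc", n = n, p = p), 5000, seed = 6)
  ## transitions out of strictly imbalanced states favour the lagging arm
  D <- t(apply(ebc, 1, function(r) cumsum(2L * r - 1L)))
  lag_chosen <- n_lag <- 0L
  for (j in 2:n) {
    behind <- D[, j - 1] != 0
    toward <- (D[, j - 1] > 0 & ebc[, j] == 0L) | (D[, j - 1] < 0 & ebc[, j] == 1L)
    lag_chosen <- lag_chosen + sum(toward[behind])
    n_lag <- n_lag + sum(behind)
  }
  phat <- lag_chosen / n_lag
  expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / n_lag))
})

test_that("stage summaries reproduce the worked allocation example", {
  al <- fig_alloc()
  expect_equal(unname(al$stage[, "nE"]), c(6, 5, 2))
  expect_equal(unname(al$stage[, "nC"]), c(2, 3, 6))
  expect_equal(unname(al$cumulative[, "nE"]), c(6, 11, 13))
  expect_equal(unname(al$cumulative[, "nC"]), c(2, 5, 11))

  pbr <- generate_sequences(rand_spec("pbr", n = 24, l = 4), 50, seed = 7)
  for (i in 1:10) {
    a <- summarize_stages(pbr[i, ], stage_plan(24, 3))
    expect_true(all(a$stage == 4L))
  }

  one <- summarize_stages(rep(1L, 8), stage_plan(8, 1))
  expect_equal(unname(one$stage[1, ]), c(8L, 0L))

  expect_error(summarize_stages(rep(1L, 10), stage_plan(24, 3)),
               "does not match")
})

test_that("exclusion rules fire on the documented configurations", {
  plan <- stage_plan(24, 3)
  a1 <- summarize_stages(c(rep(1L, 8), rep(0:1, 8)), plan)       # stage 1: 8E/0C
  expect_false(classify_sequence(a1, "cumulative", "z")$included)

  x2 <- c(rep(1:0, 4), rep(1L, 8), rep(1:0, 4))                  # stage 2: 8E/0C
  a2 <- summarize_stages(x2, plan)
  expect_true(classify_sequence(a2, "cumulative", "z")$included)
  cl <- classify_sequence(a2, "inct", "z")
  expect_false(cl$included)
  expect_match(cl$reason, "stage 2")

  x3 <- c(1L, rep(0L, 7), rep(1:0, 8))                           # stage 1: 1E/7C
  a3 <- summarize_stages(x3, plan)
  expect_true(classify_sequence(a3, "cumulative", "z")$included)
  expect_false(classify_sequence(a3, "cumulative", "t")$included)

  ## pure function: identical output on repeated calls
  expect_identical(classify_sequence(a3, "cumulative", "t"),
                   classify_sequence(a3, "cumulative", "t"))
})

test_that("single-group first-stage probabilities: closed forms match enumeration", {
  cr <- rand_spec("cr", n = 24)
  expect_equal(single_group_stage_probability(cr, 8), 2 * 0.5^8)
  ebc <- rand_spec("ebc", n = 24, p = 2/3)
  expect_equal(single_group_stage_probability(ebc, 8), (1/3)^7)
  rar <- rand_spec("rar", n = 24)
  expect_equal(single_group_stage_probability(rar, 8),
               2 * choose(16, 4) / choose(24, 12))

  for (s in c(2, 4, 8, 12)) {
    for (spec in list(cr, ebc, rar)) {
      expect_equal(single_group_stage_probability(spec, s),
                   single_group_stage_probability(spec, s, "enumerate"),
                   tolerance = 1e-12)
      kind <- spec$kind
      expect_equal(single_group_stage_probability(spec, s, "enumerate"),
                   oracle_single_group(kind, s, n = 24, p = spec$p),
                   tolerance = 1e-12)
    }
  }

  ## maximum-tolerated-imbalance designs cannot produce a monochrome stage
  ## longer than m; blocked randomization cannot exceed the block
  expect_equal(single_group_stage_probability(
    rand_spec("bsd", n = 24, m = 3), 8, "enumerate"), 0)
  expect_equal(single_group_stage_probability(
    rand_spec("chen", n = 24, p = 2/3, m = 3), 8, "enumerate"), 0)
  expect_equal(single_group_stage_probability(
    rand_spec("pbr", n = 24, l = 4), 8, "enumerate"), 0)
  expect_equal(single_group_stage_probability(
    rand_spec("bsd", n = 24, m = 3), 3, "enumerate"), 2 * 0.5^3,
    tolerance = 1e-12)

  expect_error(single_group_stage_probability(cr, 17, "enumerate"), "capped")
  expect_error(single_group_stage_probability(
    rand_spec("rpbr", n = 24, block_set = 4), 8, "enumerate"), "RPBR")
  expect_error(single_group_stage_probability(
    rand_spec("bsd", n = 24, m = 3), 8, "analytic"), "closed form")
})

test_that("sequence exports carry labels and the imbalance walk", {
  s <- generate_sequences(rand_spec("cr", n = 8), 3, seed = 8)
  df <- as.data.frame(s)
  expect_equal(nrow(df), 24)
  expect_setequal(unique(df$arm), c("E", "C"))
  d1 <- df[df$sequence_id == 1, ]
  expect_equal(d1$imbalance, cumsum(ifelse(d1$arm == "E", 1, -1)))

  one <- generate_sequence(rand_spec("cr", n = 8), seed = 9)
  expect_equal(abs(diff(c(0, one$imbalance))), rep(1, 8))
})
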