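test_that("two-sample information has the harmonic form and peaks at balance", {
  expect_equal(information(4, 4), 2)
  expect_equal(information(12, 12), 6)
  expect_equal(information(6, 2), 1.5)
  expect_error(information(0, 8), "no patients")
  for (tot in c(8, 16, 24)) {
    splits <- cbind(1:(tot - 1), tot - 1:(tot - 1))
    expect_true(all(information(splits[, 1], splits[, 2]) <=
                      information(tot / 2, tot / 2) + 1e-12))
  }
})

test_that("the joint law reproduces the worked imbalanced example", {
  law <- joint_law(fig_alloc(), "cumulative", delta = 1)
  expect_equal(law$mu, c(sqrt(1.5), sqrt(55 / 16), sqrt(143 / 24)),
               tolerance = 1e-12)
  expect_equal(law$mu, c(1.224745, 1.854050, 2.440970), tolerance = 1e-6)
  expect_equal(law$corr[1, 2], sqrt(1.5 / 3.4375), tolerance = 1e-12)
  expect_equal(joint_law(fig_alloc(), "cumulative", 0)$mu, rep(0, 3))
  expect_equal(joint_law(fig_alloc(), "inct", 0)$mu, rep(0, 3))
})

test_that("balanced equal stages make the combination test and the cumulative law coincide", {
  al <- balanced_alloc()
  for (d in c(0.5, 1, 1.4)) {
    lc <- joint_law(al, "cumulative", d)
    li <- joint_law(al, "inct", d)
    expect_equal(lc$mu, li$mu, tolerance = 1e-12)
    expect_equal(lc$corr, li$corr, tolerance = 1e-12)
  }
  dl <- gs_design(K = 3, n = 24, method = "ldm", boundary = "obf")
  di <- gs_design(K = 3, n = 24, method = "inct", boundary = "obf")
  expect_equal(conditional_power(dl, al, 1)$reject,
               conditional_power(di, al, 1)$reject, tolerance = 1e-6)
})

test_that("single-stage rejection has the univariate closed form", {
  d <- gs_design(K = 1, n = 24, method = "ldm", boundary = "obf")
  al <- balanced_alloc(24, 1)
  oc <- conditional_power(d, al, 1)
  expect_equal(oc$reject, pnorm(sqrt(6) - qnorm(0.975)), tolerance = 1e-7)
})

test_that("stopping probabilities decompose coherently", {
  d <- gs_design(K = 3, n = 24, method = "ldm", boundary = "obf",
                 futility = "nonbinding", futility_bounds = c(0, 0))
  oc <- conditional_power(d, fig_alloc(), 1, mode = "naive")
  expect_equal(sum(oc$stop_dist), 1, tolerance = 1e-7)
  expect_equal(oc$reject, sum(oc$efficacy), tolerance = 1e-12)
  expect_gte(oc$expected_stage, 1)
  expect_lte(oc$expected_stage, 3)
  ## futility mass only where bounds exist
  d0 <- gs_design(K = 3, n = 24, method = "ldm", boundary = "obf")
  oc0 <- conditional_power(d0, fig_alloc(), 1, mode = "naive")
  expect_equal(oc0$futility[1:2], c(0, 0))
  expect_gt(oc$futility[1], 0)
})

test_that("exact stopping probabilities agree with the grid-recursion oracle", {
  al <- fig_alloc()
  d <- gs_design(K = 3, n = 24, method = "ldm", boundary = "obf")
  for (delta in c(0, 1)) {
    law <- joint_law(al, "cumulative", delta)
    oc <- rejection_probability(law, d$b, d$a)
    expect_equal(oc$efficacy,
                 oracle_stage_probs(d$a, d$b, law$u, law$mu),
                 tolerance = 5e-6)
  }
  ## truncated continuation regions (futility) as well
  db <- gs_design(K = 3, n = 24, method = "ldm", boundary = "obf",
                  futility = "binding", futility_bounds = c(0, 0))
  law <- joint_law(al, "cumulative", 1)
  oc <- rejection_probability(law, db$b, db$a)
  expect_equal(oc$efficacy, oracle_stage_probs(db$a, db$b, law$u, law$mu),
               tolerance = 5e-6)
  ## combination-test law
  di <- gs_design(K = 3, n = 24, method = "inct", boundary = "obf")
  li <- joint_law(al, "inct", 1)
  expect_equal(rejection_probability(li, di$b, di$a)$reject,
               oracle_reject(di$a, di$b, li$u, li$mu), tolerance = 5e-6)
})

test_that("naive boundaries inflate the conditional level; adjustment restores it", {
  d <- gs_design(K = 3, n = 24, method = "ldm", boundary = "obf")
  al <- fig_alloc()
  expect_gt(conditional_t1e(d, al, "naive"), 0.025)
  expect_equal(conditional_t1e(d, al, "adjusted"), 0.025, tolerance = 1e-6)
  ## at balance the planned boundaries are already correct
  expect_equal(conditional_t1e(d, balanced_alloc(), "naive"), 0.025,
               tolerance = 1e-6)
  ## the combination test holds its level under any allocation
  di <- gs_design(K = 3, n = 24, method = "inct", boundary = "obf")
  expect_equal(conditional_t1e(di, al), 0.025, tolerance = 1e-6)
  ## classic bounds cannot be "adjusted"
  dc <- gs_design(K = 3, n = 24, method = "classic", boundary = "obf")
  expect_error(conditional_t1e(dc, al, "adjusted"), "naive")
  expect_gt(conditional_t1e(dc, al, "naive"), 0.025)
})

test_that("sequence-averaged characteristics: balanced procedures are invariant", {
  d <- gs_design(K = 3, n = 24, method = "ldm", boundary = "obf")
  m <- mean_operating_characteristics(rand_spec("pbr", n = 24, l = 4), d,
                                      delta = 1, n_sequences = 100, seed = 1)
  expect_equal(m$sd, 0)
  expect_equal(m$mean, conditional_power(d, balanced_alloc(), 1)$reject,
               tolerance = 1e-10)
  expect_equal(m$included, 100)
  ## null + adjusted: every sequence sits exactly at the level
  m0 <- mean_operating_characteristics(rand_spec("cr", n = 24), d,
                                       delta = 0, n_sequences = 100, seed = 2)
  expect_equal(m0$mean, 0.025, tolerance = 1e-6)
  expect_equal(m0$sd, 0, tolerance = 1e-6)
})

test_that("mean power is monotone in the effect size", {
  d <- gs_design(K = 3, n = 24, method = "ldm", boundary = "obf")
  m <- mean_operating_characteristics(rand_spec("bsd", n = 24, m = 3), d,
                                      delta = seq(0, 2, 0.5),
                                      n_sequences = 100, seed = 3)
  expect_true(all(diff(m$mean) > 0))
  di <- gs_design(K = 3, n = 24, method = "inct", boundary = "obf")
  mi <- mean_operating_characteristics(rand_spec("rar", n = 24), di,
                                       delta = seq(0, 2, 0.5),
                                       n_sequences = 100, seed = 4)
  expect_true(all(diff(mi$mean) > 0))
})

test_that("per-sequence type I errors expose the inflation pattern", {
  d <- gs_design(K = 3, n = 24, method = "ldm", boundary = "obf")
  t1 <- per_sequence_t1e(rand_spec("rar", n = 24), d, n_sequences = 200,
                         seed = 5, mode = "naive")
  expect_true(all(c("sequence_id", "t1e") %in% names(t1)))
  expect_gt(mean(t1$t1e), 0.025)
  ## imbalanced sequences sit above the nominal level, balanced ones at it
  expect_gte(min(t1$t1e), 0.025 - 1e-6)
})
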