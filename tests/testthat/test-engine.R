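params <- model_params()

test_that("a fresh agent has zero value everywhere and unit arousal", {
  st <- init_agent(params)
  expect_identical(st$w_plus, numeric(8))
  expect_identical(st$w_minus, numeric(8))
  expect_identical(st$eligibility, numeric(8))
  expect_identical(st$arousal, 1.0)
  expect_identical(st$trial_index, 0L)
  # no learning events on an unrewarded trial: state unchanged, delta zero
  out <- run_trial(st, rewarded = FALSE, drug_condition(), params)
  expect_identical(out$record$delta_trace, numeric(10))
  expect_identical(out$state$w_plus, st$w_plus)
  expect_identical(out$state$w_minus, st$w_minus)
})

test_that("the serial compound gives one feature per post-CS step", {
  expect_identical(which(features(3, params) == 1), 1L)
  expect_identical(features(2, params), numeric(8))
  expect_identical(which(features(8, params) == 1), 6L)
  expect_identical(sum(features(10, params)), 1)
  expect_error(features(0, params), "time step")
  expect_error(features(11, params), "time step")
})

test_that("drug transform scales the error magnitude and keeps dose 0 as identity", {
  expect_identical(drug_transform(0.5, drug_condition()), 0.5)
  expect_equal(drug_transform(0.5, drug_condition("reduce", 0.1)), 0.45)
  expect_equal(drug_transform(-0.5, drug_condition("reduce", 0.1)), -0.55)
  expect_equal(drug_transform(0.5, drug_condition("enhance", 0.1)), 0.55)
  expect_equal(drug_transform(-0.5, drug_condition("enhance", 0.1)), -0.45)
  expect_identical(drug_transform(0, drug_condition("enhance", 0.3)), 0)
  expect_identical(drug_transform(0.7, drug_condition("reduce", 0)), 0.7)
  # a reduce dose below 1 may never flip the sign of a positive error
  for (d in c(0.1, 0.5, 0.99)) {
    expect_gt(drug_transform(0.3, drug_condition("reduce", d)), 0)
  }
})

test_that("first rewarded trial produces the unpredicted-reward error profile", {
  st <- init_agent(params)
  out <- run_trial(st, rewarded = TRUE, drug_condition(), params)
  expect_identical(out$record$delta_at_cs, 0)
  expect_identical(out$record$delta_trace[params$reward_time], 1.0)
  # reward-time feature itself receives no credit from its own error
  expect_identical(out$state$w_plus[6], 0)
  expect_gt(out$state$w_plus[5], 0)
})

test_that("engine matches an independent brute-force recomputation", {
  # 3-trial hand-specified schedule: rewarded, omitted, rewarded
  sched <- c(TRUE, FALSE, TRUE)
  arous <- c(1, 0.6, 0.3)
  for (drug in list(c("none", 0), c("reduce", 0.1), c("enhance", 0.05))) {
    cond <- drug_condition(drug[[1]], as.numeric(drug[[2]]))
    want <- oracle_run(sched, arousal = arous,
                       drug_dir = drug[[1]], dose = as.numeric(drug[[2]]))
    got <- api_run(sched, params, cond, arousal = arous)
    expect_lt(max(abs(got$delta - want$delta)), 1e-12)
    expect_lt(max(abs(got$value - want$value)), 1e-12)
    expect_lt(max(abs(got$wp - want$wp)), 1e-12)
    expect_lt(max(abs(got$wm - want$wm)), 1e-12)
  }
})

test_that("value decomposes exactly into the two weight pathways", {
  st <- init_agent(params)
  for (i in 1:6) st <- run_trial(st, i %% 2 == 0, drug_condition(), params)$state
  for (t in 1:10) {
    x <- features(t, params)
    expect_identical(sum((st$w_plus + st$w_minus) * x),
                     sum(st$w_plus * x) + sum(st$w_minus * x))
  }
})

test_that("sign discipline holds after every update on random schedules", {
  for (seed in 1:5) {
    set.seed(seed)
    sched <- runif(40) < 0.5
    st <- init_agent(params)
    for (i in seq_along(sched)) {
      st$arousal <- runif(1)
      st <- run_trial(st, sched[i], drug_condition("enhance", 0.1), params)$state
      expect_gte(min(st$w_plus), 0)
      expect_lte(max(st$w_minus), 0)
    }
  }
})

test_that("arousal decays geometrically toward the error magnitude", {
  expect_equal(arousal_update(1, 0, 0.97), 0.97)
  expect_equal(arousal_update(0.25, -0.5, 0.97), 0.97 * 0.25 + 0.03 * 0.5)
  # fixed point: constant |delta| = c keeps arousal at c
  for (c0 in c(0.1, 0.5, 0.9)) {
    expect_equal(arousal_update(c0, -c0, 0.93), c0)
  }
  # boundedness: starting in [0, 1] with |delta| <= 1 it stays in [0, 1]
  a <- 1
  set.seed(1)
  for (i in 1:200) {
    a <- arousal_update(a, runif(1, -1, 1), 0.91)
    expect_true(a >= 0 && a <= 1)
  }
  expect_error(arousal_update(1, 0, 1), "eta")
  expect_error(arousal_update(1, 0, 0), "eta")
})

test_that("break trials decay the two pathways at their own rates", {
  st <- init_agent(params)
  st$w_plus <- rep(0.8, 8)
  st$w_minus <- rep(-0.5, 8)
  st$eligibility <- rep(0.2, 8)
  st$arousal <- 0.4
  one <- apply_break_trial(st, params)
  expect_equal(one$w_minus[1], -0.45)
  expect_equal(one$w_plus[1], 0.8 * 0.999999)
  expect_identical(one$eligibility, numeric(8))
  expect_identical(one$arousal, 0.4)
  for (i in 1:19) one <- apply_break_trial(one, params)
  expect_equal(one$w_plus[1], 0.8 * 0.999999^20, tolerance = 1e-12)
  expect_equal(one$w_minus[1], -0.5 * 0.9^20, tolerance = 1e-12)
  # negative weights lose ~88% over a 20-trial break, positives ~nothing:
  # the imbalance that produces spontaneous recovery
  expect_lt(abs(one$w_minus[1] / st$w_minus[1]), 0.125)
  expect_gt(one$w_plus[1] / st$w_plus[1], 0.99997)
})

test_that("td_step with learning disabled is a no-op with zero error", {
  st <- init_agent(params)
  st$w_plus[1] <- 0.3
  out <- td_step(st, 5, 1, drug_condition(), params, learning_enabled = FALSE)
  expect_identical(out$delta, 0)
  expect_identical(out$state, st)
})
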