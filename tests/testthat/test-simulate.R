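params <- model_params()

test_that("compiled and reference engines agree to machine precision", {
  grid <- expand.grid(p = c(0.25, 1.0), drug = c("none", "reduce"),
                      arousal = c(TRUE, FALSE), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    par_i <- model_params(use_arousal = grid$arousal[i])
    cond <- if (grid$drug[i] == "none") drug_condition() else
      drug_condition("reduce", 0.1)
    pr <- build_simulation_protocol(grid$p[i], 30, seed = i)
    a <- run_protocol(par_i, pr, cond, engine = "compiled")
    b <- run_protocol(par_i, pr, cond, engine = "reference")
    expect_lt(max(abs(a$trials$delta_cs - b$trials$delta_cs)), 1e-12)
    expect_lt(max(abs(a$delta - b$delta)), 1e-12)
    expect_lt(max(abs(a$value - b$value)), 1e-12)
    expect_lt(max(abs(a$state$w_plus - b$state$w_plus)), 1e-12)
    expect_lt(max(abs(a$state$w_minus - b$state$w_minus)), 1e-12)
  }
})

test_that("extinction-only exposure of a naive agent generates no errors", {
  acq <- session_spec("acquisition", 0.5, FALSE)  # one unrewarded trial
  ext <- session_spec("extinction", 0.5, rep(FALSE, 30))
  run <- run_protocol(params, protocol(list(acq, ext)))
  expect_true(all(run$delta == 0))
  expect_true(all(run$value == 0))
})

test_that("acquisition is monotone and orders probabilities by value", {
  pr1 <- build_simulation_protocol(1.0, 30, seed = 1)
  run1 <- run_protocol(params, pr1)
  acq <- run1$trials$delta_cs[1:30]
  expect_true(all(diff(acq) >= -1e-12))
  # asymptotic CS error increases with reward probability (20 seeds)
  mean_end <- vapply(c(0.25, 0.5, 0.75, 1.0), function(p) {
    mean(vapply(1:20, function(s) {
      run <- run_protocol(params, build_simulation_protocol(p, 30, seed = s))
      run$trials$delta_cs[30]
    }, 1))
  }, 1)
  expect_true(all(diff(mean_end) > 0))
})

test_that("higher reward probability yields higher end-of-acquisition error without arousal", {
  par0 <- model_params(use_arousal = FALSE)
  end_val <- vapply(c(0.5, 1.0), function(p) {
    run <- run_protocol(par0, build_simulation_protocol(p, 30, seed = 3))
    run$trials$delta_cs[30]
  }, 1)
  expect_gt(end_val[2], end_val[1])
})

test_that("break trials produce no prediction errors and spare arousal", {
  pr <- build_simulation_protocol(0.5, 30, seed = 2)
  run <- run_protocol(params, pr)
  brk <- which(run$trials$phase == "break")
  expect_true(all(run$delta[brk, ] == 0))
  ext1_last <- min(brk) - 1L
  # arousal recorded during the break equals the level it entered with
  expect_true(all(abs(run$trials$arousal[brk] -
                        run$trials$arousal[brk[1]]) < 1e-15))
})

test_that("arousal follows the phase rules", {
  pr <- build_simulation_protocol(0.5, 30, seed = 4)
  run <- run_protocol(params, pr)
  tr <- run$trials
  # fixed at 1 for the whole acquisition phase
  expect_true(all(tr$arousal[tr$phase == "acquisition"] == 1))
  # reset at extinction start to the learned reward expectation
  expect_equal(tr$arousal[31], abs(tr$delta_cs[30]))
  # thereafter: first-order decay toward the outcome-error magnitude
  expect_equal(tr$arousal[32],
               0.97 * tr$arousal[31] + 0.03 * abs(tr$delta_outcome[31]))
  # programmed variant uses the scheduled probability instead
  run_p <- run_protocol(model_params(arousal_init = "programmed"), pr)
  expect_equal(run_p$trials$arousal[31], 0.5)
  # disabled arousal pins the gate at 1 everywhere
  run_off <- run_protocol(model_params(use_arousal = FALSE), pr)
  expect_true(all(run_off$trials$arousal == 1))
})

test_that("dose zero reproduces the drug-free trajectory bit for bit", {
  pr <- build_simulation_protocol(0.5, 30, seed = 6)
  base <- run_protocol(params, pr, drug_condition())
  zero_e <- run_protocol(params, pr, drug_condition("enhance", 0))
  expect_identical(base$trials$delta_cs, zero_e$trials$delta_cs)
  expect_identical(base$state$w_plus, zero_e$state$w_plus)
})

test_that("spontaneous recovery appears after the break and relearning is fast", {
  pr <- build_simulation_protocol(1.0, 30, seed = 1)
  run <- run_protocol(params, pr)
  tr <- run$trials
  pre <- tr$delta_cs[100]    # last trial of first extinction
  post <- tr$delta_cs[121]   # first trial after the break
  expect_gt(post, pre)
  # fast relearning: ten reacquisition trials after extinction recover more
  # value than the first ten acquisition trials ever built
  sessions <- c(pr$sessions[1:2],
                list(session_spec("reacquisition", 1.0, rep(TRUE, 10))))
  run2 <- run_protocol(params, protocol(sessions))
  expect_gt(run2$trials$delta_cs[110], run2$trials$delta_cs[10])
})
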