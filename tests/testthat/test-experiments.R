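params <- model_params()

test_that("trials to extinction is the first criterion crossing", {
  expect_identical(trials_to_extinction(c(0.5, 0.2, 0.11, 0.05),
                                        criterion = 0.12), 3L)
  expect_identical(trials_to_extinction(c(0.5, 0.3, 0.2), criterion = 0.12),
                   NA_integer_)
  expect_identical(trials_to_extinction(c(-0.05), criterion = 0.12), 1L)
  expect_error(trials_to_extinction(numeric(0)), "empty")
})

test_that("curve classification distinguishes the four shapes", {
  expect_identical(classify_curve(c(4, 3, 2, 1)), "decreasing_PREE")
  expect_identical(classify_curve(c(1, 2, 3, 4)), "increasing")
  expect_identical(classify_curve(c(1, 3, 2.5, 1)), "inverted_U")
  expect_identical(classify_curve(c(2, 2.1, 2, 2.2)), "flat_or_mixed")
  # margins below tolerance do not count
  expect_identical(classify_curve(c(3, 2.8, 2.6, 2.4), tolerance = 0.5),
                   "flat_or_mixed")
  expect_error(classify_curve(c(1, 2)), "3 probability levels")
})

test_that("sweeps are deterministic given the base seed", {
  a <- sweep_extinction(params, n_acq = 30, etas = 0.97, n_seeds = 5, seed = 9)
  b <- sweep_extinction(params, n_acq = 30, etas = 0.97, n_seeds = 5, seed = 9)
  expect_identical(a$results, b$results)
  expect_identical(a$labels, b$labels)
  expect_identical(a$meta$seeds, 9L + 0:4)
  expect_identical(nrow(a$results), 4L * 5L)
  # every cell aggregates the same seeds
  expect_true(all(table(a$results$probability) == 5L))
})

test_that("runs that never reach criterion are censored, not truncated silently", {
  # an impossible criterion censors everything at the phase length
  par_hard <- model_params(extinction_criterion = 1e-6)
  sw <- sweep_extinction(par_hard, probabilities = c(0.25, 0.5, 0.75),
                         n_acq = 10, etas = 0.97, n_seeds = 3, seed = 1)
  expect_true(all(sw$results$censored))
  expect_true(all(sw$results$trials_to_extinction == 70L))
  expect_identical(sw$labels$label, "flat_or_mixed")
})

test_that("dose zero column of a dose response equals the drug-free sweep", {
  dr <- dose_response(params, direction = "reduce", doses = c(0, 0.1),
                      n_seeds = 4, seed = 2)
  sw <- sweep_extinction(params, n_acq = 30, etas = params$eta,
                         n_seeds = 4, seed = 2)
  d0 <- dr$results[dr$results$dose == 0, ]
  expect_identical(d0$trials_to_extinction, sw$results$trials_to_extinction)
  expect_identical(d0$end_value, sw$results$end_value)
  expect_error(dose_response(params, direction = "reduce", doses = c(0, 1)),
               "below 1")
})

test_that("eta threshold picks the smallest qualifying decay factor", {
  sw <- list(labels = data.frame(eta = c(0.91, 0.95, 0.99),
                                 n_acq = 30L,
                                 label = c("increasing", "inverted_U",
                                           "inverted_U")))
  class(sw) <- "sweep_result"
  expect_identical(eta_threshold(sw, "inverted_U"), 0.95)
  expect_identical(eta_threshold(sw, "decreasing_PREE"), NA_real_)
})

test_that("per-subject normalization gives unit row means", {
  m <- rbind(c(10, 20, 30, 40), c(5, 5, 5, 5))
  nm <- normalize_by_subject_mean(m)
  expect_equal(nm[1, ], c(0.4, 0.8, 1.2, 1.6))
  expect_equal(nm[2, ], rep(1, 4))
  set.seed(1)
  r <- matrix(rexp(28) + 0.1, 7)
  expect_equal(unname(rowMeans(normalize_by_subject_mean(r))), rep(1, 7))
  expect_error(normalize_by_subject_mean(rbind(c(0, 0, 0))), "zero")
  expect_error(normalize_by_subject_mean(rbind(c(NA, NA), c(1, 2))),
               "all-missing")
})

test_that("reference normalization anchors the reference level at 1", {
  out <- normalize_to_reference(c(6, 9, 6, 3),
                                probabilities = c(0.25, 0.5, 0.75, 1))
  expect_equal(unname(out), c(2, 3, 2, 1))
  expect_equal(unname(out[4]), 1)
  expect_error(normalize_to_reference(c(1, 2, NA),
                                      probabilities = c(0.25, 0.5, 1)),
               "criterion")
  expect_error(normalize_to_reference(c(1, 2, 3),
                                      probabilities = c(0.25, 0.5, 0.75),
                                      reference = 1),
               "not present")
})
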