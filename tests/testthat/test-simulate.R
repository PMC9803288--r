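test_that("simulation is seed-deterministic and respects the design", {
  a <- simulate_ecwm(300, 250, pi = 0.3, design = ecwm_design(0.2), seed = 11)
  b <- simulate_ecwm(300, 250, pi = 0.3, design = ecwm_design(0.2), seed = 11)
  expect_identical(a$records, b$records)
  expect_identical(counts_as_vector <- unlist(a$counts[c("n21", "n11", "n22", "n12")]),
                   unlist(b$counts[c("n21", "n11", "n22", "n12")]))
  expect_identical(nrow(a$records), 550L)
  expect_identical(sum(a$records$s == 1), 300L)
  # truth columns are retained
  expect_true(all(c("carrier", "unrelated", "self_protective",
                    "random_responder") %in% names(a$records)))
})

test_that("cell frequencies converge to the model probabilities", {
  n <- 200000
  sim <- simulate_ecwm(n, n, pi = 0.3, design = ecwm_design(0.8), seed = 2)
  expect_equal(sim$counts$n21 / n, 0.38, tolerance = 0.01)
  expect_equal(sim$counts$n12 / n, 0.38, tolerance = 0.01)
  est <- moment_pooled(sim$counts)
  expect_equal(est$pi_hat, 0.3, tolerance = 0.01)
})

test_that("pure random responding pushes both response shares to one half", {
  sim <- simulate_ecwm(50000, 50000, pi = 0.9, design = ecwm_design(0.2),
                       random_responder_frac = 1, seed = 3)
  expect_equal(sim$counts$n21 / 50000, 0.5, tolerance = 0.02)
  expect_equal(sim$counts$n22 / 50000, 0.5, tolerance = 0.02)
  expect_equal(moment_pooled(sim$counts)$pi_hat, 0.5, tolerance = 0.03)
})

test_that("informed self-protection biases the naive estimate as predicted", {
  sim <- simulate_ecwm(100000, 100000, pi = 0.3, design = ecwm_design(0.8),
                       theta_c = 0.5, theta_nc = 0, seed = 4)
  expect_lt(abs(moment_pooled(sim$counts)$pi_hat - 0.1), 0.01)
  # ... and remains invisible to the goodness-of-fit test (exact version
  # on expected counts is in the acceptance suite)
  g <- gof_test(sim$counts)
  expect_gt(g$p_value, 0.001)
})

test_that("direct-question simulation underreports as configured", {
  full <- simulate_dq(100000, pi = 0.3, dq_report_prob = 1, seed = 5)
  expect_equal(full$n_yes / 100000, 0.3, tolerance = 0.01)
  half <- simulate_dq(100000, pi = 0.3, dq_report_prob = 0.5, seed = 5)
  expect_equal(half$n_yes / 100000, 0.15, tolerance = 0.01)
  none <- simulate_dq(1000, pi = 0.3, dq_report_prob = 0, seed = 5)
  expect_identical(none$n_yes, 0L)
})

test_that("recovery study reports unbiased estimates with nominal coverage", {
  rec <- recovery_study(reps = 150, n1 = 1000, n2 = 1000, pi = 0.3,
                        design = ecwm_design(0.2), seed = 6)
  expect_identical(rec$method, c("moment_weighted", "mle"))
  for (i in 1:2) {
    expect_lt(abs(rec$bias[i]), 0.015)
    expect_gte(rec$rmse[i], abs(rec$bias[i]))
    expect_gt(rec$ci_coverage[i], 0.90)
  }
  # contaminated generator recovers the predicted biased value
  rec_sp <- recovery_study(reps = 60, n1 = 3000, n2 = 3000, pi = 0.3,
                           design = ecwm_design(0.8), theta_c = 0.5,
                           seed = 7)
  expect_equal(rec_sp$mean_estimate[1], 0.1, tolerance = 0.01)
})

test_that("goodness-of-fit test has power against asymmetric response bias", {
  cal <- gof_calibration(reps = 150, n1 = 367, n2 = 367, pi = 0.3,
                         design = ecwm_design(0.8), flip_subsample1 = TRUE,
                         seed = 8)
  expect_gt(cal$rejection_rate, 0.9)
})

test_that("analytic power behaves like a power function", {
  d <- ecwm_design(0.8)
  # vanishing alternative: power collapses to the significance level
  tiny <- ecwm_power(1e-8, d, n_grid = 500)
  expect_equal(tiny$grid$power, 0.05, tolerance = 1e-3)
  # monotone in n, and the minimum sample size honors the target
  pw <- ecwm_power(0.2, d, n_grid = c(50, 100, 200, 400, 734))
  expect_true(all(diff(pw$grid$power) >= 0))
  expect_true(is.na(pw$min_n) ||
                all(pw$grid$power[pw$grid$n < pw$min_n] < pw$power_target))
  expect_error(ecwm_power(0.2, ecwm_design(0.2), n_grid = 0), "n_grid > 0")
})
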