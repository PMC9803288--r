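test_that("response probabilities follow the crosswise kernel", {
  d <- ecwm_design(0.8)
  expect_equal(response_prob(2, 1, 0, d), 0.2)
  expect_equal(response_prob(2, 1, 0.3, d), 0.38)
  # cross-sub-sample symmetry of the complementary design
  expect_equal(response_prob(1, 2, 0.3, d), 0.38)
  expect_equal(response_prob(1, 1, 0.3, d) + response_prob(2, 1, 0.3, d), 1)
  expect_error(response_prob(3, 1, 0.3, d), "must be 1 or 2")
})

test_that("log-likelihood reduces to known closed forms", {
  x <- fixture_counts("Drug use1-Q1")
  n <- x$n21 + x$n11 + x$n22 + x$n12
  records <- data.frame(
    y = rep(c(2, 1, 2, 1), c(x$n21, x$n11, x$n22, x$n12)),
    s = rep(c(1, 1, 2, 2), c(x$n21, x$n11, x$n22, x$n12)))
  X <- matrix(1, nrow = n)
  # beta = 0 puts every respondent at pi = 1/2, where both responses have
  # probability 1/2 regardless of the design
  expect_equal(ecwm_loglik(0, records$y, records$s, X, x$design),
               n * log(0.5))
  # at any pi the respondent-level likelihood equals the multinomial one
  for (pi in c(0.1, 0.262, 0.9)) {
    mult <- sum(c(x$n21, x$n11, x$n22, x$n12) *
                  log(c(response_prob(2, 1, pi, x$design),
                        response_prob(1, 1, pi, x$design),
                        response_prob(2, 2, pi, x$design),
                        response_prob(1, 2, pi, x$design))))
    expect_equal(ecwm_loglik(qlogis(pi), records$y, records$s, X, x$design),
                 mult)
  }
})

test_that("intercept-only MLE equals the pooled moment estimator when interior", {
  df <- three_studies()
  for (i in seq_len(nrow(df))) {
    x <- crosswise_counts(df$n21[i], df$n11[i], df$n22[i], df$n12[i],
                          design = ecwm_design(df$p1[i]), label = df$label[i])
    mom <- moment_pooled(x)
    if (mom$pi_hat > 0 && mom$pi_hat < 1) {
      fit <- ecwm_fit(x)
      expect_false(fit$boundary)
      expect_equal(fit$pi_hat, mom$pi_hat, tolerance = 1e-6)
      mle <- prevalence_from_fit(fit)
      expect_equal(mle$variance, mom$variance, tolerance = 1e-6)
    }
  }
})

test_that("counts fit equals the fit on expanded respondent-level data", {
  x <- fixture_counts("Drug use1-Q1")
  records <- data.frame(
    y = rep(c(2, 1, 2, 1), c(x$n21, x$n11, x$n22, x$n12)),
    s = rep(c(1, 1, 2, 2), c(x$n21, x$n11, x$n22, x$n12)))
  f_counts <- ecwm_fit(x)
  f_records <- ecwm_fit(records, design = x$design)
  expect_equal(f_records$loglik, f_counts$loglik, tolerance = 1e-8)
  expect_equal(plogis(f_records$beta[[1]]), f_counts$pi_hat, tolerance = 1e-6)
})

test_that("sub-sample covariate reproduces the per-arm moment estimates", {
  x <- fixture_counts("Drug use1-Q1")
  records <- data.frame(
    y = rep(c(2, 1, 2, 1), c(x$n21, x$n11, x$n22, x$n12)),
    s = rep(c(1, 1, 2, 2), c(x$n21, x$n11, x$n22, x$n12)))
  fit <- ecwm_fit(records, design = x$design, formula = ~ factor(s))
  pi1 <- plogis(fit$beta[[1]])
  pi2 <- plogis(fit$beta[[1]] + fit$beta[[2]])
  expect_equal(pi1, moment_subsample(x$n21, x$n21 + x$n11, 0.2),
               tolerance = 1e-6)
  expect_equal(pi2, moment_subsample(x$n22, x$n22 + x$n12, 0.8),
               tolerance = 1e-6)
})

test_that("prevalence back-transform matches the published interval", {
  est <- prevalence_from_fit(ecwm_fit(fixture_counts("Covid-F1")))
  expect_equal(round(100 * est$pi_hat, 1), 33.4)
  expect_equal(round(100 * c(est$ci_low, est$ci_high), 1), c(27.8, 38.9))
  # observed-information delta-method SE agrees with the closed-form
  # variance within 2% on near-balanced data
  obs <- prevalence_from_fit(ecwm_fit(fixture_counts("Covid-F1")),
                             variance = "observed")
  expect_equal(sqrt(obs$variance), sqrt(est$variance), tolerance = 0.02)
})

test_that("degenerate and boundary prevalence handling", {
  # beta = 0 with zero variance pins the estimate at one half
  fit0 <- structure(
    list(beta = c("(Intercept)" = 0),
         vcov = matrix(0, 1, 1), loglik = -1, converged = TRUE,
         boundary = FALSE, n_obs = 10, design = ecwm_design(0.2),
         model = "intercept", pi_hat = 0.5),
    class = "ecwm_fit")
  est <- prevalence_from_fit(fit0, variance = "observed")
  expect_equal(est$pi_hat, 0.5)
  expect_equal(c(est$ci_low, est$ci_high), c(0.5, 0.5))
  # a table far below the non-carrier line in both arms drives the MLE to
  # the boundary at zero
  bnd <- crosswise_counts(90, 10, 10, 90, design = ecwm_design(0.2))
  fit <- ecwm_fit(bnd)
  expect_true(fit$boundary)
  expect_identical(fit$pi_hat, 0)
  est <- prevalence_from_fit(fit)
  expect_true(est$boundary)
  expect_identical(est$ci_low, 0)
})
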