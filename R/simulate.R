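# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.null(seed) && (!is.numeric(seed) || length(seed) != 1L)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate respondent-level extended crosswise data
#'
#' Generates one ECWM question under a behavioral model with three layers:
#' truthful crosswise responding, informed self-protection, and random
#' responding. Each respondent draws a carrier status `Bernoulli(pi)` and
#' an unrelated-question answer `Bernoulli(ps)`; the truthful response is
#' 2 ("TWO Yes or TWO No") when the two answers agree, else 1. With
#' probability `theta_c` (carriers) or `theta_nc` (non-carriers) the
#' respondent instead emits the non-incriminating response of their
#' sub-sample (the response a non-carrier gives most often: 1 where
#' `ps > 0.5`, 2 where `ps < 0.5`). Finally, a fraction
#' `random_responder_frac` of respondents replaces their response with a
#' fair coin flip, which biases estimates toward 50%. Sub-sample sizes are
#' fixed, not binomially split.
#'
#' @param n1,n2 Sub-sample sizes.
#' @param pi True prevalence of the sensitive characteristic.
#' @param design An [ecwm_design()] or a `p1` value.
#' @param theta_c,theta_nc Informed self-protection probabilities for
#'   carriers and non-carriers.
#' @param random_responder_frac Fraction answering uniformly at random.
#' @param seed Optional integer seed; identical seeds give identical data.
#' @param label Question label for the counts object.
#' @return A list with `records` (data frame: `y`, `s`, plus the latent
#'   truth columns `carrier`, `unrelated`, `self_protective`,
#'   `random_responder`) and `counts` (a [crosswise_counts()]).
#' @examples
#' sim <- simulate_ecwm(200, 200, pi = 0.3, design = ecwm_design(0.2), seed = 1)
#' sim$counts
#' @export
simulate_ecwm <- function(n1, n2, pi, design, theta_c = 0, theta_nc = 0,
                          random_responder_frac = 0, seed = NULL,
                          label = "simulated") {
  design <- as_ecwm_design(design, control = TRUE)
  stopifnot(n1 >= 0, n2 >= 0, n1 + n2 > 0,
            pi >= 0, pi <= 1, theta_c >= 0, theta_c <= 1,
            theta_nc >= 0, theta_nc <= 1,
            random_responder_frac >= 0, random_responder_frac <= 1)
  with_seed(seed, {
    n <- n1 + n2
    s <- rep(c(1L, 2L), c(n1, n2))
    ps <- ifelse(s == 1L, design$p1, design$p2)
    carrier <- stats::rbinom(n, 1L, pi)
    unrelated <- stats::rbinom(n, 1L, ps)
    y <- ifelse(carrier == unrelated, 2L, 1L)
    # the non-incriminating (safe) response of each sub-sample
    safe <- ifelse(ps > 0.5, 1L, 2L)
    sp <- stats::runif(n) < ifelse(carrier == 1L, theta_c, theta_nc)
    y[sp] <- safe[sp]
    rr <- stats::runif(n) < random_responder_frac
    y[rr] <- sample(c(1L, 2L), sum(rr), replace = TRUE)
    records <- data.frame(y = y, s = s, carrier = carrier,
                          unrelated = unrelated, self_protective = sp,
                          random_responder = rr)
    counts <- crosswise_counts(
      sum(y == 2L & s == 1L), sum(y == 1L & s == 1L),
      sum(y == 2L & s == 2L), sum(y == 1L & s == 2L),
      design = design, label = label)
    list(records = records, counts = counts)
  })
}

#' Simulate direct-question data with underreporting
#'
#' Carriers admit the sensitive characteristic with probability
#' `dq_report_prob` (underreporting); non-carriers never falsely confess.
#' The "Yes" count is therefore `Binomial(n, pi * dq_report_prob)`.
#'
#' @param n Sample size.
#' @param pi True prevalence.
#' @param dq_report_prob Probability that a carrier answers "Yes".
#' @param seed Optional integer seed.
#' @return A list with `n_yes` and `n_no`.
#' @export
simulate_dq <- function(n, pi, dq_report_prob = 1, seed = NULL) {
  stopifnot(n >= 0, pi >= 0, pi <= 1,
            dq_report_prob >= 0, dq_report_prob <= 1)
  with_seed(seed, {
    n_yes <- stats::rbinom(1L, n, pi * dq_report_prob)
    list(n_yes = n_yes, n_no = n - n_yes)
  })
}

#' Parameter recovery study
#'
#' Repeatedly simulates ECWM data and re-estimates the prevalence with the
#' pooled moment estimator and the intercept-only MLE, summarizing bias,
#' root-mean-square error and 95% confidence interval coverage against the
#' generating value. With contamination (`theta_c`, `theta_nc`,
#' `random_responder_frac`) the summary quantifies the bias the naive
#' estimators inherit.
#'
#' @inheritParams simulate_ecwm
#' @param reps Number of Monte Carlo replicates.
#' @return A data frame with one row per method: `method`,
#'   `mean_estimate`, `bias`, `rmse`, `ci_coverage`, `reps`.
#' @examples
#' recovery_study(reps = 20, n1 = 300, n2 = 300, pi = 0.3,
#'         design = ecwm_design(0.2), seed = 1)
#' @export
recovery_study <- function(reps, n1, n2, pi, design, theta_c = 0, theta_nc = 0,
                    random_responder_frac = 0, seed = NULL) {
  stopifnot(reps >= 1)
  design <- as_ecwm_design(design, control = TRUE)
  with_seed(seed, {
    est <- matrix(NA_real_, reps, 2L,
                  dimnames = list(NULL, c("moment_weighted", "mle")))
    cover <- matrix(NA, reps, 2L)
    for (r in seq_len(reps)) {
      sim <- simulate_ecwm(n1, n2, pi, design, theta_c, theta_nc,
                           random_responder_frac)
      mom <- tryCatch(moment_pooled(sim$counts), error = function(e) {
        stop(sprintf("replicate %d: %s", r, conditionMessage(e)),
             call. = FALSE)
      })
      mle <- prevalence_from_fit(ecwm_fit(sim$counts))
      est[r, ] <- c(mom$pi_hat, mle$pi_hat)
      cover[r, ] <- c(mom$ci_low <= pi && pi <= mom$ci_high,
                      mle$ci_low <= pi && pi <= mle$ci_high)
    }
    data.frame(method = colnames(est),
               mean_estimate = colMeans(est),
               bias = colMeans(est) - pi,
               rmse = sqrt(colMeans((est - pi)^2)),
               ci_coverage = colMeans(cover),
               reps = reps, row.names = NULL)
  })
}

#' Calibration of the goodness-of-fit test
#'
#' Monte Carlo estimate of the rejection rate of the likelihood-ratio
#' goodness-of-fit test at the chi-squared(1) critical value. Under the
#' null model (no contamination) the rate should sit near the nominal
#' level. Data generated under informed self-protection still pass the
#' test — the contamination shifts both sub-samples coherently — whereas
#' biases that break the cross-sub-sample symmetry are detected.
#'
#' @inheritParams simulate_ecwm
#' @param reps Number of Monte Carlo replicates.
#' @param critical Rejection threshold for the LR statistic; the default
#'   is the upper 5% point of chi-squared(1).
#' @param flip_subsample1 If `TRUE`, responses in sub-sample 1 are flipped
#'   (`y -> 3 - y`) after generation: an asymmetric response bias the test
#'   has power against.
#' @return A list with `rejection_rate`, `stats` (the LR statistics), and
#'   `reps`.
#' @export
gof_calibration <- function(reps, n1, n2, pi, design, theta_c = 0,
                            theta_nc = 0, random_responder_frac = 0,
                            critical = stats::qchisq(0.95, 1),
                            flip_subsample1 = FALSE, seed = NULL) {
  stopifnot(reps >= 1)
  design <- as_ecwm_design(design, control = TRUE)
  with_seed(seed, {
    stats_out <- numeric(reps)
    for (r in seq_len(reps)) {
      sim <- simulate_ecwm(n1, n2, pi, design, theta_c, theta_nc,
                           random_responder_frac)
      counts <- sim$counts
      if (flip_subsample1) {
        counts <- crosswise_counts(counts$n11, counts$n21,
                                   counts$n22, counts$n12,
                                   design = design, label = counts$label)
      }
      stats_out[r] <- gof_test(counts)$lr_stat
    }
    list(rejection_rate = mean(stats_out > critical),
         stats = stats_out, reps = reps, critical = critical)
  })
}

#' Power and minimum sample size of the ECWM
#'
#' Analytic power of the two-sided Wald test of `H0: pi = 0` against
#' `pi = pi_alt`, using the closed-form ECWM variance at each hypothesis:
#' the null rejects when `|pi_hat| > z_{alpha/2} * se0` and `pi_hat` is
#' approximately normal with mean `pi_alt` and the alternative's standard
#' error. A Monte Carlo mode re-estimates the power by simulation with the
#' same decision rule.
#'
#' @param pi_alt Alternative prevalence in (0, 1).
#' @param design An [ecwm_design()] or a `p1` value.
#' @param n_grid Total sample sizes to evaluate.
#' @param alpha Two-sided significance level.
#' @param power_target Power level defining the minimum sample size.
#' @param allocation Fraction of the sample in sub-sample 1.
#' @param mc_reps If positive, also compute Monte Carlo power at each `n`.
#' @param seed Seed for the Monte Carlo mode.
#' @return A list with `grid` (data frame `n`, `power`, and `mc_power`
#'   when requested) and `min_n` (smallest grid `n` reaching
#'   `power_target`, `NA` if none does).
#' @examples
#' ecwm_power(0.2, ecwm_design(0.8), n_grid = c(100, 400, 734))
#' @export
ecwm_power <- function(pi_alt, design, n_grid, alpha = 0.05,
                       power_target = 0.80, allocation = 0.5,
                       mc_reps = 0, seed = NULL) {
  design <- as_ecwm_design(design)
  stopifnot(pi_alt > 0, pi_alt < 1, alpha > 0, alpha < 1,
            allocation > 0, allocation < 1, all(n_grid > 0))
  if (design$p1 == 0.5) stop("p1 = 0.5 gives infinite variance", call. = FALSE)
  zc <- stats::qnorm(1 - alpha / 2)
  p1 <- design$p1
  analytic <- vapply(n_grid, function(n) {
    se0 <- sqrt(ecwm_variance(0, n, p1))
    se1 <- sqrt(ecwm_variance(pi_alt, n, p1))
    crit <- zc * se0
    stats::pnorm((pi_alt - crit) / se1) + stats::pnorm((-crit - pi_alt) / se1)
  }, numeric(1))
  grid <- data.frame(n = n_grid, power = analytic)
  if (mc_reps > 0) {
    grid$mc_power <- with_seed(seed, vapply(n_grid, function(n) {
      n1 <- round(n * allocation)
      n2 <- n - n1
      crit <- zc * sqrt(ecwm_variance(0, n, p1))
      rej <- vapply(seq_len(mc_reps), function(r) {
        sim <- simulate_ecwm(n1, n2, pi_alt, design)
        abs(moment_pooled(sim$counts)$pi_hat) > crit
      }, logical(1))
      mean(rej)
    }, numeric(1)))
  }
  reached <- grid$n[grid$power >= power_target]
  list(grid = grid,
       min_n = if (length(reached)) min(reached) else NA_real_,
       alpha = alpha, pi_alt = pi_alt, power_target = power_target)
}
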