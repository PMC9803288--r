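#' Response probability of the crosswise model
#'
#' Probability of observing response `y` in sub-sample `s` for a respondent
#' with prevalence (carrier probability) `pi`:
#' `ps * pi + (1 - ps) * (1 - pi)` for `y = 2` and its complement for
#' `y = 1`. Vectorized over `y`, `s` and `pi`.
#'
#' @param y Response, 1 ("ONE Yes") or 2 ("TWO Yes or TWO No").
#' @param s Sub-sample, 1 or 2.
#' @param pi Carrier probability in `[0, 1]`.
#' @param design An [ecwm_design()] or a `p1` value.
#' @return Probability of the observed response.
#' @examples
#' response_prob(2, 1, 0.3, ecwm_design(0.8))
#' @export
response_prob <- function(y, s, pi, design) {
  design <- as_ecwm_design(design, control = TRUE)
  if (!all(y %in% c(1, 2)) || !all(s %in% c(1, 2))) {
    stop("'y' and 's' must be 1 or 2", call. = FALSE)
  }
  stopifnot(all(pi >= 0), all(pi <= 1))
  ps <- ifelse(s == 1, design$p1, design$p2)
  p2 <- ps * pi + (1 - ps) * (1 - pi)
  ifelse(y == 2, p2, 1 - p2)
}

# multinomial log-likelihood of a counts table at per-sub-sample
# prevalences (pi1, pi2); 0 * log(0) treated as 0
loglik_counts <- function(counts, pi1, pi2 = pi1) {
  design <- counts$design
  pr <- c(response_prob(2, 1, pi1, design), response_prob(1, 1, pi1, design),
          response_prob(2, 2, pi2, design), response_prob(1, 2, pi2, design))
  nv <- counts_vector(counts)
  sum(ifelse(nv > 0, nv * log(pr), 0))
}

#' Log-likelihood of the ECWM logistic regression model
#'
#' Sum over respondents of the log response probability, with individual
#' carrier probabilities `pi_i = plogis(x_i' beta)`.
#'
#' @param beta Coefficient vector on the logit scale.
#' @param y,s Response and sub-sample vectors (values 1 or 2).
#' @param x Model matrix (leading column of ones for the intercept).
#' @param design An [ecwm_design()].
#' @param weights Optional nonnegative case weights.
#' @return The log-likelihood (a nonpositive number for 0 < p1 < 1).
#' @export
ecwm_loglik <- function(beta, y, s, x, design, weights = NULL) {
  x <- as.matrix(x)
  if (is.null(weights)) weights <- rep(1, length(y))
  pi_i <- stats::plogis(drop(x %*% beta))
  sum(weights * log(response_prob(y, s, pi_i, design)))
}

new_ecwm_fit <- function(beta, vcov, loglik, converged, boundary, n_obs,
                         design, model, pi_hat, counts = NULL) {
  structure(
    list(beta = beta, vcov = vcov, loglik = loglik, converged = converged,
         boundary = boundary, n_obs = n_obs, design = design, model = model,
         pi_hat = pi_hat, counts = counts),
    class = "ecwm_fit")
}

#' @export
print.ecwm_fit <- function(x, ...) {
  cat(sprintf("ECWM maximum likelihood fit (%s), n = %d\n",
              x$model, as.integer(x$n_obs)))
  cat(sprintf("  log-likelihood: %.4f%s%s\n", x$loglik,
              if (x$boundary) "  [boundary solution]" else "",
              if (!x$converged) "  [NOT converged]" else ""))
  if (!is.null(x$beta) && all(is.finite(x$beta))) {
    cat("  coefficients (logit scale):\n")
    print(round(x$beta, 4))
  }
  if (!is.null(x$pi_hat)) {
    cat(sprintf("  prevalence: %s\n",
                paste(sprintf("%.4f", x$pi_hat), collapse = ", ")))
  }
  invisible(x)
}

BOUNDARY_TOL <- 1e-6

# intercept-only ML fit on aggregated counts: one-dimensional likelihood
# maximized over pi in [0, 1]; endpoints checked explicitly so that
# boundary solutions are found exactly
fit_counts_intercept <- function(counts) {
  sz <- counts_sizes(counts)
  if (sz$n1 <= 0 || sz$n2 <= 0) {
    stop("both sub-samples must be nonempty", call. = FALSE)
  }
  f <- function(pi) loglik_counts(counts, pi)
  opt <- stats::optimize(f, interval = c(0, 1), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  # Newton polish of the interior candidate: the score is rational in pi
  pi_cand <- opt$maximum
  nv <- counts_vector(counts)
  p1 <- counts$design$p1
  cc <- c(2 * p1 - 1, 1 - 2 * p1, 1 - 2 * p1, 2 * p1 - 1)
  aa <- c(1 - p1, p1, p1, 1 - p1)
  for (step in 1:3) {
    pr <- aa + cc * pi_cand
    score <- sum(nv * cc / pr)
    info <- sum(nv * (cc / pr)^2)
    if (!is.finite(score) || !is.finite(info) || info <= 0) break
    pi_new <- pi_cand + score / info
    if (pi_new <= 0 || pi_new >= 1) break
    pi_cand <- pi_new
  }
  if (pi_cand > 0 && pi_cand < 1 && f(pi_cand) >= opt$objective) {
    opt <- list(maximum = pi_cand, objective = f(pi_cand))
  }
  cand_pi <- c(opt$maximum, 0, 1)
  cand_ll <- c(opt$objective, f(0), f(1))
  best <- which.max(cand_ll)
  pi_hat <- cand_pi[best]
  ll <- cand_ll[best]
  boundary <- pi_hat < BOUNDARY_TOL || pi_hat > 1 - BOUNDARY_TOL
  if (boundary) pi_hat <- round(pi_hat)
  beta <- stats::qlogis(pi_hat)
  vcov <- matrix(NA_real_, 1L, 1L, dimnames = list("(Intercept)", "(Intercept)"))
  if (!boundary) {
    # observed information on the logit scale by central differences
    h <- 1e-4
    g <- function(b) loglik_counts(counts, stats::plogis(b))
    d2 <- (g(beta + h) - 2 * g(beta) + g(beta - h)) / h^2
    if (is.finite(d2) && d2 < 0) vcov[1L, 1L] <- -1 / d2
  }
  new_ecwm_fit(beta = stats::setNames(beta, "(Intercept)"), vcov = vcov,
               loglik = ll, converged = TRUE, boundary = boundary,
               n_obs = sz$n, design = counts$design, model = "intercept",
               pi_hat = pi_hat, counts = counts)
}

# saturated-in-sub-sample ML fit on counts: within each sub-sample the
# constrained MLE is the moment estimate clipped into [0, 1]
fit_counts_subsample <- function(counts) {
  sz <- counts_sizes(counts)
  if (sz$n1 <= 0 || sz$n2 <= 0) {
    stop("both sub-samples must be nonempty", call. = FALSE)
  }
  design <- counts$design
  pi1 <- clip01(moment_subsample(counts$n21, sz$n1, design$p1))
  pi2 <- clip01(moment_subsample(counts$n22, sz$n2, design$p2))
  ll <- loglik_counts(counts, pi1, pi2)
  boundary <- any(c(pi1, pi2) < BOUNDARY_TOL | c(pi1, pi2) > 1 - BOUNDARY_TOL)
  new_ecwm_fit(beta = NULL, vcov = NULL, loglik = ll, converged = TRUE,
               boundary = boundary, n_obs = sz$n, design = design,
               model = "subsample", pi_hat = c(pi1, pi2), counts = counts)
}

#' Maximum likelihood estimation of the extended crosswise model
#'
#' Fits the ECWM by maximizing the randomized-response likelihood. Two
#' input forms are supported: an aggregated [crosswise_counts()] table
#' (intercept-only or sub-sample-saturated model), and a respondent-level
#' data frame with columns `y` and `s` plus covariates, for logistic
#' regression of the sensitive characteristic on covariates via a formula.
#'
#' With counts input the intercept-only likelihood is maximized over the
#' closed interval `[0, 1]` so that boundary solutions (prevalence 0 or 1)
#' are detected exactly; at an interior optimum the estimate coincides
#' with the pooled moment estimator. Respondent-level fits are
#' unconstrained on the logit scale (BFGS with analytic gradient); the
#' covariance matrix is the inverse of the numerically differentiated
#' observed information.
#'
#' @param data A [crosswise_counts()] table or a data frame with columns
#'   `y`, `s` and covariates.
#' @param ... Passed to methods.
#' @return An object of class `ecwm_fit` with elements `beta`, `vcov`,
#'   `loglik`, `converged`, `boundary`, `n_obs`, `pi_hat`.
#' @examples
#' q1 <- crosswise_counts(249, 112, 150, 223, design = ecwm_design(0.2))
#' ecwm_fit(q1)
#' @export
ecwm_fit <- function(data, ...) UseMethod("ecwm_fit")

#' @rdname ecwm_fit
#' @param model For counts input: `"intercept"` (single prevalence) or
#'   `"subsample"` (separate prevalence per sub-sample, the saturated
#'   model of the goodness-of-fit test).
#' @export
ecwm_fit.crosswise_counts <- function(data, model = c("intercept", "subsample"),
                                      ...) {
  model <- match.arg(model)
  switch(model,
         intercept = fit_counts_intercept(data),
         subsample = fit_counts_subsample(data))
}

#' @rdname ecwm_fit
#' @param design An [ecwm_design()]; required for data-frame input.
#' @param formula Model formula for the carrier probability, e.g. `~ 1` or
#'   `~ factor(s)`; terms are looked up in `data`.
#' @param weights Optional nonnegative case weights.
#' @param maxit Maximum BFGS iterations.
#' @export
ecwm_fit.data.frame <- function(data, design, formula = ~1, weights = NULL,
                                maxit = 200L, ...) {
  stopifnot(all(c("y", "s") %in% names(data)))
  design <- as_ecwm_design(design, control = TRUE)
  y <- data$y
  s <- data$s
  if (!all(y %in% c(1, 2)) || !all(s %in% c(1, 2))) {
    stop("'y' and 's' must take values 1 or 2", call. = FALSE)
  }
  x <- stats::model.matrix(formula, data)
  if (is.null(weights)) weights <- rep(1, nrow(x))
  # response 2 has probability a + b * pi with a = 1 - ps, b = 2 ps - 1
  ps <- ifelse(s == 1, design$p1, design$p2)
  a <- ifelse(y == 2, 1 - ps, ps)
  b <- ifelse(y == 2, 2 * ps - 1, 1 - 2 * ps)

  negll <- function(beta) {
    pi_i <- stats::plogis(drop(x %*% beta))
    -sum(weights * log(a + b * pi_i))
  }
  grad <- function(beta) {
    pi_i <- stats::plogis(drop(x %*% beta))
    w <- weights * b * pi_i * (1 - pi_i) / (a + b * pi_i)
    -drop(crossprod(x, w))
  }
  start <- rep(0, ncol(x))
  opt <- stats::optim(start, negll, grad, method = "BFGS", hessian = TRUE,
                      control = list(maxit = maxit, reltol = 1e-12))
  beta <- stats::setNames(opt$par, colnames(x))
  vcov <- tryCatch(solve(opt$hessian), error = function(e) {
    matrix(NA_real_, ncol(x), ncol(x))
  })
  dimnames(vcov) <- list(colnames(x), colnames(x))
  pi_i <- stats::plogis(drop(x %*% beta))
  boundary <- all(pi_i < BOUNDARY_TOL) || all(pi_i > 1 - BOUNDARY_TOL)
  new_ecwm_fit(beta = beta, vcov = vcov, loglik = -opt$value,
               converged = opt$convergence == 0L, boundary = boundary,
               n_obs = sum(weights), design = design, model = deparse(formula),
               pi_hat = if (ncol(x) == 1L) stats::plogis(beta[[1L]]) else NULL)
}

#' Prevalence estimate from a fitted ECWM model
#'
#' Back-transforms a fitted logit to the probability scale and attaches a
#' variance and 95% Wald interval (endpoints truncated to `[0, 1]`). Two
#' variance conventions are available: `"expected"` (the closed-form ECWM
#' variance evaluated at the estimate — the default, available for
#' intercept-only fits) and `"observed"` (delta method,
#' `pi (1 - pi) * se(x' beta)`, from the inverse observed information).
#'
#' @param fit An [ecwm_fit()] result.
#' @param at Covariate vector at which to evaluate a regression fit;
#'   defaults to the intercept-only case.
#' @param variance `"expected"` or `"observed"`.
#' @return A [prevalence_estimate()] with `method = "mle"`.
#' @examples
#' f1 <- crosswise_counts(249, 145, 186, 247, design = ecwm_design(0.2))
#' prevalence_from_fit(ecwm_fit(f1))
#' @export
prevalence_from_fit <- function(fit, at = NULL,
                                variance = c("expected", "observed")) {
  stopifnot(inherits(fit, "ecwm_fit"))
  variance <- match.arg(variance)
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  if (is.null(at)) {
    if (is.null(fit$beta) || length(fit$beta) != 1L) {
      stop("'at' is required for fits with covariates", call. = FALSE)
    }
    at <- 1
  }
  if (length(at) > 1L || variance == "observed") {
    eta <- drop(sum(at * fit$beta))
    pi_hat <- stats::plogis(eta)
    var_eta <- drop(t(at) %*% fit$vcov %*% at)
    v <- (pi_hat * (1 - pi_hat))^2 * var_eta
    if (fit$boundary || !is.finite(v)) {
      pi_hat <- clip01(if (is.null(fit$pi_hat)) pi_hat else fit$pi_hat[1L])
      v <- ecwm_variance(pi_hat, fit$n_obs, fit$design$p1)
    }
    return(prevalence_estimate(pi_hat, v, method = "mle",
                               boundary = fit$boundary, n = fit$n_obs))
  }
  pi_hat <- fit$pi_hat[1L]
  v <- ecwm_variance(pi_hat, fit$n_obs, fit$design$p1)
  prevalence_estimate(pi_hat, v, method = "mle", boundary = fit$boundary,
                      n = fit$n_obs)
}

#' Likelihood-ratio goodness-of-fit test of the ECWM
#'
#' The complementary randomization probabilities leave one degree of
#' freedom for misfit: the test compares the intercept-only model against
#' the model with a separate prevalence per sub-sample. `lr_stat` is twice
#' the log-likelihood difference; `g2_stat` is the discrepancy statistic
#' `2 * sum(n_ys * log(n_ys / fitted_ys))` with fitted counts from the
#' intercept-only fit (the `0 * log(0) = 0` convention applies). The two
#' coincide whenever the null estimate is interior. On a boundary solution
#' the likelihood-ratio statistic collapses to zero while `g2_stat` stays
#' positive; the `boundary` flag marks this case. The p-value refers
#' `lr_stat` to a chi-squared distribution on 1 degree of freedom; a
#' significant value indicates instruction non-adherence (response biases
#' whose effects on the two sub-samples do not cancel).
#'
#' @param counts A [crosswise_counts()] object.
#' @return An object of class `gof_result` with fields `lr_stat`,
#'   `g2_stat`, `df`, `p_value`, `boundary`.
#' @examples
#' q1 <- crosswise_counts(249, 112, 150, 223, design = ecwm_design(0.2))
#' gof_test(q1)
#' @export
gof_test <- function(counts) {
  stopifnot(inherits(counts, "crosswise_counts"))
  null_fit <- fit_counts_intercept(counts)
  full_fit <- fit_counts_subsample(counts)
  lr <- max(0, 2 * (full_fit$loglik - null_fit$loglik))
  sz <- counts_sizes(counts)
  design <- counts$design
  fitted <- c(sz$n1 * response_prob(2, 1, null_fit$pi_hat, design),
              sz$n1 * response_prob(1, 1, null_fit$pi_hat, design),
              sz$n2 * response_prob(2, 2, null_fit$pi_hat, design),
              sz$n2 * response_prob(1, 2, null_fit$pi_hat, design))
  nv <- counts_vector(counts)
  g2 <- 2 * sum(ifelse(nv > 0, nv * log(nv / fitted), 0))
  structure(
    list(lr_stat = lr, g2_stat = g2, df = 1L,
         p_value = stats::pchisq(lr, df = 1L, lower.tail = FALSE),
         boundary = null_fit$boundary,
         null_fit = null_fit, full_fit = full_fit),
    class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("ECWM goodness-of-fit: LR = %.2f, G2 = %.2f, df = %d, p = %.3f%s\n",
              x$lr_stat, x$g2_stat, x$df, x$p_value,
              if (x$boundary) "  [boundary: LR set to 0]" else ""))
  invisible(x)
}
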