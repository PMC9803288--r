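Z95 <- stats::qnorm(0.975)

clip01 <- function(x) pmin(1, pmax(0, x))

#' Prevalence estimate container
#'
#' Bundles a point estimate with its variance and a 95% Wald confidence
#' interval. Moment point estimates are reported unclipped — a negative
#' estimate is informative about sampling error or response bias — while
#' the interval endpoints are truncated to `[0, 1]`.
#'
#' @param pi_hat Point estimate (may fall outside `[0, 1]` for moment
#'   estimators).
#' @param variance Estimated variance of `pi_hat`.
#' @param method One of `"moment_weighted"`, `"moment_matrix"`, `"mle"`,
#'   `"binomial"`.
#' @param boundary Logical; `TRUE` when an ML solution lies on the boundary
#'   of the parameter space.
#' @param n Sample size behind the estimate.
#' @return An object of class `prevalence_estimate` with fields `pi_hat`,
#'   `variance`, `ci_low`, `ci_high`, `method`, `boundary`, `n`.
#' @export
prevalence_estimate <- function(pi_hat, variance, method, boundary = FALSE,
                                n = NA_real_) {
  stopifnot(is.finite(pi_hat), is.finite(variance), variance >= 0)
  se <- sqrt(variance)
  structure(
    list(pi_hat = pi_hat,
         variance = variance,
         ci_low = clip01(pi_hat - Z95 * se),
         ci_high = clip01(pi_hat + Z95 * se),
         method = method,
         boundary = isTRUE(boundary),
         n = n),
    class = "prevalence_estimate")
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  cat(sprintf("Prevalence estimate (%s%s): %.1f%% (95%% CI %.1f, %.1f)\n",
              x$method, if (x$boundary) ", boundary" else "",
              100 * x$pi_hat, 100 * x$ci_low, 100 * x$ci_high))
  invisible(x)
}

#' Per-sub-sample moment estimator
#'
#' Inverts the crosswise response model within one sub-sample:
#' `(n2s / ns - 1 + ps) / (2 * ps - 1)`, where `n2s / ns` is the observed
#' proportion of "TWO Yes or TWO No" responses. The value is returned
#' unclipped and can be negative (when the observed proportion falls on the
#' wrong side of `1 - ps`) or exceed one.
#'
#' @param n2s Count of response 2 in the sub-sample.
#' @param ns Sub-sample size.
#' @param ps Randomization probability of the sub-sample.
#' @return The raw moment estimate of the prevalence.
#' @examples
#' moment_subsample(249, 361, 0.2)
#' @export
moment_subsample <- function(n2s, ns, ps) {
  if (any(ns <= 0)) stop("empty sub-sample: ns must be positive", call. = FALSE)
  if (any(ps == 0.5)) {
    stop("invalid design: ps = 0.5 makes the prevalence unidentifiable",
         call. = FALSE)
  }
  (n2s / ns - 1 + ps) / (2 * ps - 1)
}

# variance of the pooled estimator; pi is clipped into [0,1] inside
# pi*(1-pi) so that out-of-range moment estimates keep a nonnegative
# variance
ecwm_variance <- function(pi, n, p1) {
  pi <- clip01(pi)
  (pi * (1 - pi) + p1 * (1 - p1) / (2 * p1 - 1)^2) / n
}

#' Pooled (weighted-average) moment estimator
#'
#' The classical ECWM estimator: the per-sub-sample moment estimates are
#' combined with weights proportional to the sub-sample sizes,
#' `pi_hat = (n1 * pi1 + n2 * pi2) / n`. Its variance,
#' `(pi (1 - pi) + p1 (1 - p1) / (2 p1 - 1)^2) / n`, coincides with the
#' variance of the single-sample crosswise model; the unknown `pi` is
#' replaced by the pooled estimate (clipped into `[0, 1]`).
#'
#' @param counts A [crosswise_counts()] object.
#' @return A [prevalence_estimate()] with `method = "moment_weighted"`.
#' @examples
#' q1 <- crosswise_counts(249, 112, 150, 223, design = ecwm_design(0.2))
#' moment_pooled(q1)
#' @export
moment_pooled <- function(counts) {
  stopifnot(inherits(counts, "crosswise_counts"))
  sz <- counts_sizes(counts)
  if (sz$n1 <= 0 || sz$n2 <= 0) {
    stop("both sub-samples must be nonempty", call. = FALSE)
  }
  p1 <- counts$design$p1
  pi1 <- moment_subsample(counts$n21, sz$n1, p1)
  pi2 <- moment_subsample(counts$n22, sz$n2, counts$design$p2)
  pi_hat <- (sz$n1 * pi1 + sz$n2 * pi2) / sz$n
  prevalence_estimate(pi_hat, ecwm_variance(pi_hat, sz$n, p1),
                      method = "moment_weighted", n = sz$n)
}

#' Generalized-inverse moment estimator
#'
#' Estimates the prevalence in one step as `2 * P^- %*% pihat_ys`, where
#' `P^-` is the Moore-Penrose generalized inverse of the 4 x 2 transition
#' matrix and `pihat_ys = n_ys / n` are the unconditional response
#' proportions. Its variance is element (1, 1) of
#' `4 / n * P^- (Diag(pihat_ys) - pihat_ys pihat_ys') (P^-)'`.
#' With equal sub-sample sizes this estimator coincides with
#' [moment_pooled()] to machine precision.
#'
#' @param counts A [crosswise_counts()] object.
#' @return A [prevalence_estimate()] with `method = "moment_matrix"`.
#' @examples
#' f1 <- crosswise_counts(249, 145, 186, 247, design = ecwm_design(0.2))
#' moment_matrix(f1)
#' @export
moment_matrix <- function(counts) {
  stopifnot(inherits(counts, "crosswise_counts"))
  sz <- counts_sizes(counts)
  if (sz$n <= 0) stop("empty table", call. = FALSE)
  if (counts$design$p1 == 0.5) {
    stop("invalid design: p1 = 0.5", call. = FALSE)
  }
  p_inv <- MASS::ginv(transition_matrix(counts$design))
  prop <- counts_vector(counts) / sz$n
  est <- drop(2 * p_inv %*% prop)
  vmat <- 4 / sz$n * p_inv %*% (diag(prop) - tcrossprod(prop)) %*% t(p_inv)
  prevalence_estimate(est[1L], vmat[1L, 1L],
                      method = "moment_matrix", n = sz$n)
}
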