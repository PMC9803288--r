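#' Direct-question prevalence estimate
#'
#' Binomial proportion for a conventional yes/no item, with Wald variance
#' `pi (1 - pi) / n` and a 95% interval truncated to `[0, 1]`. This is the
#' comparison condition for the "more-is-better" validation criterion: a
#' privacy-protecting design should recover more "Yes" answers than direct
#' questioning on sensitive items, and the same share on non-sensitive
#' ones.
#'
#' @param n_yes,n_no Nonnegative counts of "Yes" and "No" answers.
#' @return A [prevalence_estimate()] with `method = "binomial"`.
#' @examples
#' dq_estimate(37, 341)
#' @export
dq_estimate <- function(n_yes, n_no) {
  stopifnot(n_yes >= 0, n_no >= 0)
  n <- n_yes + n_no
  if (n <= 0) stop("empty direct-question table", call. = FALSE)
  pi_hat <- n_yes / n
  prevalence_estimate(pi_hat, pi_hat * (1 - pi_hat) / n,
                      method = "binomial", n = n)
}

new_comparison <- function(delta, se_delta, statistic = NULL, df = NULL) {
  if (is.null(statistic)) {
    z <- if (se_delta > 0) delta / se_delta else 0
    p <- 2 * stats::pnorm(-abs(z))
    out <- list(delta = delta, se_delta = se_delta, z = z,
                p_value = p, two_sided = TRUE)
  } else {
    out <- list(delta = delta, se_delta = se_delta, statistic = statistic,
                df = df, p_value = stats::pchisq(statistic, df,
                                                 lower.tail = FALSE),
                two_sided = TRUE)
  }
  structure(out, class = "ecwm_comparison")
}

#' @export
print.ecwm_comparison <- function(x, ...) {
  if (!is.null(x$z)) {
    cat(sprintf("Difference of prevalences: %.1f pp, z = %.2f, p = %.3f\n",
                100 * x$delta, x$z, x$p_value))
  } else {
    cat(sprintf("Chi-squared test: X2 = %.2f, df = %d, p = %.3f\n",
                x$statistic, x$df, x$p_value))
  }
  invisible(x)
}

# z test on the difference of two independent prevalence estimates
compare_estimates <- function(e1, e2) {
  stopifnot(inherits(e1, "prevalence_estimate"),
            inherits(e2, "prevalence_estimate"))
  if (!is.finite(e1$variance) || !is.finite(e2$variance)) {
    stop("both estimates must carry variances", call. = FALSE)
  }
  new_comparison(e1$pi_hat - e2$pi_hat, sqrt(e1$variance + e2$variance))
}

#' Compare an ECWM estimate with a direct-question estimate
#'
#' Two-sample z test of the difference `pi_ECWM - pi_DQ`, with the
#' variance of the difference taken as the sum of the two estimation
#' variances (closed-form ECWM variance plus binomial variance). A
#' significantly positive difference on a sensitive item supports the
#' "more-is-better" criterion.
#'
#' @param ecwm A [prevalence_estimate()] from [moment_pooled()] or
#'   [prevalence_from_fit()].
#' @param dq A [prevalence_estimate()] from [dq_estimate()].
#' @return An `ecwm_comparison` with fields `delta`, `se_delta`, `z`,
#'   `p_value`.
#' @examples
#' f1 <- crosswise_counts(249, 145, 186, 247, design = ecwm_design(0.2))
#' compare_ecwm_dq(moment_pooled(f1), dq_estimate(37, 341))
#' @export
compare_ecwm_dq <- function(ecwm, dq) compare_estimates(ecwm, dq)

#' Compare two independent ECWM estimates
#'
#' Two-sample z test between question formats (for instance question vs
#' statement wording, or factual vs judgmental framing) asked of
#' independent samples under the same randomization design.
#'
#' @param e1,e2 [prevalence_estimate()] objects from independent samples.
#' @return An `ecwm_comparison`; `delta` is `e1$pi_hat - e2$pi_hat`.
#' @export
compare_two_ecwm <- function(e1, e2) compare_estimates(e1, e2)

#' Pearson chi-squared test on two error rates
#'
#' Compares the error (or any event) rates of two independent groups via
#' the Pearson chi-squared statistic on the 2 x 2 table, one degree of
#' freedom, without continuity correction. Used for contrasting control
#' question error rates between survey designs; the statistic equals the
#' squared two-proportion z statistic.
#'
#' @param k1,n1 Events and size of group 1.
#' @param k2,n2 Events and size of group 2.
#' @return An `ecwm_comparison` with fields `statistic`, `df`, `p_value`.
#' @examples
#' error_rate_chi2(50, 100, 25, 100)
#' @export
error_rate_chi2 <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2L, byrow = TRUE)
  if (any(colSums(tab) == 0)) {
    stop("degenerate margin: statistic undefined", call. = FALSE)
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  new_comparison(delta = k1 / n1 - k2 / n2,
                 se_delta = NA_real_, statistic = stat, df = 1L)
}
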