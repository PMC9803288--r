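#' Randomization design of the extended crosswise model
#'
#' An ECWM survey splits the sample into two sub-samples with complementary
#' probabilities of a "Yes" answer to the unrelated question: sub-sample 1
#' has probability `p1`, sub-sample 2 has `p2 = 1 - p1`. The complementarity
#' creates the degree of freedom used by the goodness-of-fit test.
#'
#' `p1 = 0.5` is rejected because every estimator divides by `2 * p1 - 1`.
#' The degenerate values 0 and 1 are only meaningful for control items
#' (known-prevalence questions) and are rejected unless `control = TRUE`.
#'
#' @param p1 Probability of a "Yes" answer to the unrelated question in
#'   sub-sample 1.
#' @param control Allow the degenerate probabilities 0 and 1 used for
#'   control questions.
#' @return An object of class `ecwm_design` with elements `p1` and `p2`.
#' @examples
#' ecwm_design(1 / 5)
#' @export
ecwm_design <- function(p1, control = FALSE) {
  stopifnot(is.numeric(p1), length(p1) == 1L, is.finite(p1))
  if (p1 < 0 || p1 > 1) {
    stop("'p1' must lie in [0, 1]", call. = FALSE)
  }
  if (p1 == 0.5) {
    stop("invalid design: p1 = 0.5 makes the prevalence unidentifiable ",
         "(estimators divide by 2*p1 - 1)", call. = FALSE)
  }
  if (!control && (p1 == 0 || p1 == 1)) {
    stop("p1 in {0, 1} is only allowed for control-question designs ",
         "(use control = TRUE)", call. = FALSE)
  }
  structure(list(p1 = p1, p2 = 1 - p1), class = "ecwm_design")
}

#' @export
print.ecwm_design <- function(x, ...) {
  cat(sprintf("ECWM randomization design: p1 = %g, p2 = %g\n", x$p1, x$p2))
  invisible(x)
}

as_ecwm_design <- function(x, control = FALSE) {
  if (inherits(x, "ecwm_design")) x else ecwm_design(x, control = control)
}

#' Transition matrix of the extended crosswise model
#'
#' The 4 x 2 matrix mapping the carrier / non-carrier status probabilities
#' `(pi, 1 - pi)` onto the four conditional response probabilities, in the
#' fixed row order (2|1, 1|1, 2|2, 1|2) where response 2 is "TWO Yes or
#' TWO No" and response 1 is "ONE Yes". Because `p2 = 1 - p1`, rows 1 and 4
#' coincide, as do rows 2 and 3: the model implies the cross-sub-sample
#' symmetry on which the identifiability argument for informed
#' self-protection rests.
#'
#' @param design An [ecwm_design()] or a `p1` value.
#' @return A 4 x 2 numeric matrix with dimnames.
#' @examples
#' transition_matrix(ecwm_design(0.8))
#' @export
transition_matrix <- function(design) {
  design <- as_ecwm_design(design, control = TRUE)
  p1 <- design$p1
  m <- matrix(c(p1,     1 - p1,
                1 - p1, p1,
                1 - p1, p1,
                p1,     1 - p1),
              nrow = 4L, byrow = TRUE)
  dimnames(m) <- list(c("2|1", "1|1", "2|2", "1|2"),
                      c("carrier", "non-carrier"))
  m
}

#' Transition matrix under informed self-protection
#'
#' Informed self-protection means emitting the non-incriminating response
#' for one's sub-sample, which requires knowing which response is
#' incriminating. Under the convention `p1 > p2` the incriminating response
#' is 2 in sub-sample 1 and 1 in sub-sample 2. Carriers self-protect with
#' probability `theta_c`, non-carriers with `theta_nc`. The resulting
#' matrix retains the equality of rows 1 and 4 and of rows 2 and 3, so
#' data generated from it are indistinguishable from an ordinary ECWM with
#' a smaller prevalence: `theta_c` and `theta_nc` are unidentified, and the
#' goodness-of-fit test has no power against this contamination.
#'
#' Each column is a probability distribution (entries within a sub-sample
#' sum to one) for any admissible `theta`.
#'
#' @param design An [ecwm_design()] with `p1 > 0.5`.
#' @param theta_c,theta_nc Self-protection probabilities of carriers and
#'   non-carriers, in `[0, 1]`.
#' @return A 4 x 2 numeric matrix in the same row order as
#'   [transition_matrix()].
#' @examples
#' sp_transition_matrix(ecwm_design(0.8), theta_c = 0.5)
#' @export
sp_transition_matrix <- function(design, theta_c = 0, theta_nc = 0) {
  design <- as_ecwm_design(design)
  if (design$p1 <= 0.5) {
    stop("informed self-protection is defined for p1 > p2; supply the ",
         "design with p1 > 0.5", call. = FALSE)
  }
  stopifnot(theta_c >= 0, theta_c <= 1, theta_nc >= 0, theta_nc <= 1)
  p1 <- design$p1
  r14 <- c(p1 * (1 - theta_c), (1 - theta_nc) * (1 - p1))
  r23 <- c(1 - p1 * (1 - theta_c), p1 + theta_nc * (1 - p1))
  m <- rbind(r14, r23, r23, r14)
  dimnames(m) <- list(c("2|1", "1|1", "2|2", "1|2"),
                      c("carrier", "non-carrier"))
  m
}

#' Probability limit of the naive estimator under informed self-protection
#'
#' When a fraction of respondents self-protects, the ordinary moment (and
#' ML) estimator converges not to the prevalence `pi` but to
#' `pi - (pi * p1 * theta_c + (1 - pi) * (1 - p1) * theta_nc) / (2 * p1 - 1)`,
#' which for `theta_nc = 0` reduces to
#' `pi * (1 - p1 * theta_c / (2 * p1 - 1))`. Both sub-samples are biased by
#' the same amount, so the contamination is invisible to the
#' goodness-of-fit test. The limit can be negative.
#'
#' @inheritParams sp_transition_matrix
#' @param pi True prevalence of the sensitive characteristic.
#' @return The large-sample limit of the pooled moment estimator.
#' @examples
#' sp_expected_naive_estimate(0.3, ecwm_design(0.8), theta_c = 0.5)
#' @export
sp_expected_naive_estimate <- function(pi, design, theta_c = 0, theta_nc = 0) {
  design <- as_ecwm_design(design)
  stopifnot(pi >= 0, pi <= 1)
  p1 <- design$p1
  # apply the moment estimator to the contaminated response probabilities
  q <- sp_transition_matrix(design, theta_c, theta_nc)
  prob21 <- unname(drop(q["2|1", ] %*% c(pi, 1 - pi)))
  (prob21 - 1 + p1) / (2 * p1 - 1)
}
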