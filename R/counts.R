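#' Observed crosswise counts for one question
#'
#' The aggregated data of one ECWM question: a 2 x 2 table of response
#' (2 = "TWO Yes or TWO No", 1 = "ONE Yes") by sub-sample, together with
#' the randomization design. `n21` and `n11` are the response-2 and
#' response-1 counts in sub-sample 1 (randomization probability `p1`),
#' `n22` and `n12` the same in sub-sample 2.
#'
#' @param n21,n11,n22,n12 Nonnegative integer counts.
#' @param design An [ecwm_design()] or a `p1` value.
#' @param label Optional question label carried through reports.
#' @return An object of class `crosswise_counts`.
#' @examples
#' crosswise_counts(249, 112, 150, 223, design = ecwm_design(0.2))
#' @export
crosswise_counts <- function(n21, n11, n22, n12, design, label = NULL) {
  counts <- c(n21 = n21, n11 = n11, n22 = n22, n12 = n12)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  design <- as_ecwm_design(design, control = TRUE)
  structure(
    list(label = if (is.null(label)) NA_character_ else as.character(label),
         n21 = as.numeric(n21), n11 = as.numeric(n11),
         n22 = as.numeric(n22), n12 = as.numeric(n12),
         design = design),
    class = "crosswise_counts")
}

#' @export
print.crosswise_counts <- function(x, ...) {
  lab <- if (is.na(x$label)) "" else paste0(" [", x$label, "]")
  cat(sprintf("Crosswise counts%s (p1 = %g):\n", lab, x$design$p1))
  m <- matrix(c(x$n21, x$n11, x$n22, x$n12), nrow = 2L,
              dimnames = list(response = c("2", "1"),
                              `sub-sample` = c("1", "2")))
  print(m)
  invisible(x)
}

# sub-sample sizes and total
counts_sizes <- function(x) {
  n1 <- x$n21 + x$n11
  n2 <- x$n22 + x$n12
  list(n1 = n1, n2 = n2, n = n1 + n2)
}

# counts as the 4-vector in the canonical row order (2|1, 1|1, 2|2, 1|2)
counts_vector <- function(x) {
  c(x$n21, x$n11, x$n22, x$n12)
}

# swap sub-sample labels (and the design with them); the estimators are
# invariant under this relabeling
flip_counts <- function(x) {
  crosswise_counts(x$n22, x$n12, x$n21, x$n11,
                   design = ecwm_design(x$design$p2, control = TRUE),
                   label = x$label)
}
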