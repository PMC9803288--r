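COUNT_COLS <- c("label", "p1", "n21", "n11", "n22", "n12")

#' Read a count-table CSV
#'
#' Reads aggregated ECWM count tables, one question per row, with the
#' schema `label, p1, n21, n11, n22, n12` (extra columns are allowed and
#' ignored). Rows are validated — nonnegative integer counts,
#' `p1 != 0.5` — and malformed rows are reported with their row number.
#'
#' @param path Path to a CSV file.
#' @return A list of [crosswise_counts()] objects (empty for an empty
#'   file, with a warning).
#' @export
read_counts <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(COUNT_COLS, names(df))
  if (length(missing)) {
    stop(sprintf("missing columns in '%s': %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    warning(sprintf("'%s' contains no data rows", path), call. = FALSE)
    return(list())
  }
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    out[[i]] <- tryCatch(
      crosswise_counts(df$n21[i], df$n11[i], df$n22[i], df$n12[i],
                       design = ecwm_design(df$p1[i], control = TRUE),
                       label = df$label[i]),
      error = function(e) {
        stop(sprintf("row %d of '%s': %s", i, path, conditionMessage(e)),
             call. = FALSE)
      })
  }
  names(out) <- df$label
  out
}

#' Write a count-table CSV
#'
#' Inverse of [read_counts()]: writes a list of [crosswise_counts()] in
#' the canonical schema. `write_counts()` then `read_counts()` round-trips
#' exactly.
#'
#' @param counts A list of [crosswise_counts()] objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  if (inherits(counts, "crosswise_counts")) counts <- list(counts)
  df <- do.call(rbind, lapply(counts, function(x) {
    data.frame(label = x$label, p1 = x$design$p1, n21 = x$n21, n11 = x$n11,
               n22 = x$n22, n12 = x$n12)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Bundled observed response frequencies of three UK surveys
#'
#' The aggregated responses of three online validation surveys run in the
#' UK in 2020: Study I (controlled substance use, question vs statement
#' wording; ECWM only), Study II (COVID-19 lockdown compliance, factual vs
#' judgmental wording; ECWM and direct questioning) and Study III
#' (controlled substance use; ECWM and direct questioning). Every ECWM
#' question used the complementary randomization probabilities 1/5 and
#' 4/5; sub-sample 1 is the 1/5 arm.
#'
#' @param study `"all"` or a subset of `c("I", "II", "III")`.
#' @return A data frame with columns `label`, `study`, `format`, `p1`,
#'   `n21`, `n11`, `n22`, `n12`, `dq_yes`, `dq_no` (the direct-question
#'   columns are `NA` for Study I, which had no DQ condition).
#' @examples
#' head(three_studies())
#' @export
three_studies <- function(study = "all") {
  path <- system.file("extdata", "three_studies.csv", package = "crosswise",
                      mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(study, "all")) {
    stopifnot(all(study %in% c("I", "II", "III")))
    df <- df[df$study %in% study, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

# one fixture row -> crosswise_counts
row_to_counts <- function(row) {
  crosswise_counts(row$n21, row$n11, row$n22, row$n12,
                   design = ecwm_design(row$p1, control = TRUE),
                   label = row$label)
}

#' Per-question estimation and comparison report
#'
#' The machine-readable analogue of a published results table: for every
#' question, the intercept-only ECWM maximum likelihood estimate with its
#' 95% interval, the goodness-of-fit statistics, and — where a
#' direct-question condition exists — the DQ estimate, the difference of
#' prevalences and its z test. Prevalences and the difference are reported
#' in percent at full precision; use [format_table2()] for a display
#' rounded the conventional way (percentages to 1 decimal, statistics to
#' 2, p-values to 3).
#'
#' @param x A data frame in the layout of [three_studies()]; the
#'   `dq_yes` / `dq_no` columns are optional.
#' @return A data frame with one row per question: `label`, `dq_est`,
#'   `dq_low`, `dq_high`, `ecwm_est`, `ecwm_low`, `ecwm_high`, `g2`,
#'   `gof_p`, `delta`, `z`, `z_p`. Rows whose estimation fails carry `NA`
#'   and a warning, without aborting the batch.
#' @examples
#' run_table2(three_studies("III"))
#' @export
run_table2 <- function(x) {
  stopifnot(is.data.frame(x), all(COUNT_COLS %in% names(x)))
  has_dq <- all(c("dq_yes", "dq_no") %in% names(x))
  rows <- lapply(seq_len(nrow(x)), function(i) {
    row <- x[i, , drop = FALSE]
    out <- data.frame(label = row$label, dq_est = NA_real_, dq_low = NA_real_,
                      dq_high = NA_real_, ecwm_est = NA_real_,
                      ecwm_low = NA_real_, ecwm_high = NA_real_,
                      g2 = NA_real_, gof_p = NA_real_, delta = NA_real_,
                      z = NA_real_, z_p = NA_real_)
    tryCatch({
      counts <- row_to_counts(row)
      est <- prevalence_from_fit(ecwm_fit(counts))
      gof <- gof_test(counts)
      out$ecwm_est <- 100 * est$pi_hat
      out$ecwm_low <- 100 * est$ci_low
      out$ecwm_high <- 100 * est$ci_high
      out$g2 <- gof$g2_stat
      out$gof_p <- gof$p_value
      if (has_dq && !is.na(row$dq_yes) && !is.na(row$dq_no)) {
        dq <- dq_estimate(row$dq_yes, row$dq_no)
        cmp <- compare_ecwm_dq(est, dq)
        out$dq_est <- 100 * dq$pi_hat
        out$dq_low <- 100 * dq$ci_low
        out$dq_high <- 100 * dq$ci_high
        out$delta <- 100 * cmp$delta
        out$z <- cmp$z
        out$z_p <- cmp$p_value
      }
    }, error = function(e) {
      warning(sprintf("question '%s': %s", row$label, conditionMessage(e)),
              call. = FALSE)
    })
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Format a report for display
#'
#' Rounds a [run_table2()] report to the conventional display precision:
#' percentages to 1 decimal, test statistics to 2, p-values to 3.
#'
#' @param report A data frame from [run_table2()].
#' @return A character data frame ready for printing.
#' @export
format_table2 <- function(report) {
  fmt <- function(v, d) ifelse(is.na(v), "-", formatC(v, format = "f", digits = d))
  data.frame(
    label = report$label,
    dq = ifelse(is.na(report$dq_est), "-",
                sprintf("%s (%s, %s)", fmt(report$dq_est, 1),
                        fmt(report$dq_low, 1), fmt(report$dq_high, 1))),
    ecwm = sprintf("%s (%s, %s)", fmt(report$ecwm_est, 1),
                   fmt(report$ecwm_low, 1), fmt(report$ecwm_high, 1)),
    g2 = fmt(report$g2, 2),
    gof_p = fmt(report$gof_p, 3),
    delta = fmt(report$delta, 1),
    z = fmt(report$z, 2),
    z_p = fmt(report$z_p, 3))
}
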