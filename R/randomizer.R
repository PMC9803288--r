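#' Eligible first-sequence numbers
#'
#' The first sequence of a number-sequence randomizer item is drawn from
#' the two-digit numbers 10–99 with the easy-to-memorize values removed:
#' repeated-digit ("master") numbers 11, 22, ..., 99 and multiples of ten
#' 10, 20, ..., 90. (Single-digit numbers are excluded by construction.)
#' That leaves exactly 72 admissible numbers.
#'
#' @return An integer vector of the 72 admissible numbers.
#' @examples
#' length(eligible_pool())
#' @export
eligible_pool <- function() {
  pool <- 10:99
  pool[pool %% 11 != 0 & pool %% 10 != 0]
}

new_sequence_pair <- function(first_seq, second_seq) {
  overlap <- sum(first_seq %in% second_seq)
  structure(
    list(first_seq = as.integer(first_seq),
         second_seq = as.integer(second_seq),
         overlap = overlap,
         implied_p = overlap / length(first_seq)),
    class = "sequence_pair")
}

#' @export
print.sequence_pair <- function(x, ...) {
  cat(sprintf("Number-sequence randomizer item (L = %d, implied p = %d/%d):\n",
              length(x$first_seq), x$overlap, length(x$first_seq)))
  cat("  first:  ", paste(x$first_seq, collapse = " "), "\n")
  cat("  second: ", paste(x$second_seq, collapse = " "), "\n")
  invisible(x)
}

#' Generate a number-sequence randomizer item
#'
#' Builds the pair of sequences defining one unrelated question: the
#' respondent memorizes a number from the first sequence and later reports
#' whether it appears in the second. Exactly `L * target_p` first-sequence
#' numbers reappear, so the randomization probability is known by design —
#' overlap 1, 2 or 3 for `p = 1/5` and 4, 8 or 12 for `p = 4/5` at lengths
#' 5, 10 and 15. The first sequence is sampled from [eligible_pool()];
#' filler numbers of the second sequence come from 1–99 excluding the
#' first sequence (memorability restrictions apply only where a number
#' must be memorized). For `target_p = 1` (control items) the second
#' sequence is the first in a different order; `target_p = 0` shares no
#' numbers.
#'
#' @param L Sequence length: 5, 10 or 15.
#' @param target_p Designed reappearance probability: 0, 1/5, 4/5 or 1.
#' @param seed Optional integer seed for reproducible sequences.
#' @return A `sequence_pair` with fields `first_seq`, `second_seq`,
#'   `overlap`, `implied_p`.
#' @examples
#' generate_pair(10, 1 / 5, seed = 42)
#' @export
generate_pair <- function(L, target_p, seed = NULL) {
  if (!L %in% c(5L, 10L, 15L)) {
    stop("'L' must be 5, 10 or 15", call. = FALSE)
  }
  admissible_p <- c(0, 1 / 5, 4 / 5, 1)
  if (length(target_p) != 1L || !any(abs(target_p - admissible_p) < 1e-12)) {
    stop("'target_p' must be one of 0, 1/5, 4/5, 1", call. = FALSE)
  }
  k <- as.integer(round(L * target_p))
  with_seed(seed, {
    first_seq <- sample(eligible_pool(), L)
    if (k == L) {
      # control item: same numbers, different order
      repeat {
        second_seq <- sample(first_seq)
        if (!identical(second_seq, first_seq)) break
      }
    } else {
      reappear <- sample(first_seq, k)
      fillers <- sample(setdiff(1:99, first_seq), L - k)
      second_seq <- sample(c(reappear, fillers))
    }
    new_sequence_pair(first_seq, second_seq)
  })
}

#' Validate a randomizer item against the construction rules
#'
#' Recomputes the overlap from the two sequences and checks every design
#' rule: admissible lengths, first-sequence membership of the eligible
#' pool, absence of duplicates, second-sequence range, and an implied
#' probability among the designed values.
#'
#' @param pair A `sequence_pair` (or a list with `first_seq` and
#'   `second_seq`).
#' @return A list with `implied_p`, `overlap`, `valid`, and a character
#'   vector `violations` (empty when the item is well formed).
#' @examples
#' validate_pair(generate_pair(5, 4 / 5, seed = 1))
#' @export
validate_pair <- function(pair) {
  first_seq <- pair$first_seq
  second_seq <- pair$second_seq
  violations <- character()
  l1 <- length(first_seq)
  if (!l1 %in% c(5L, 10L, 15L)) {
    violations <- c(violations, sprintf("first sequence length %d not in {5, 10, 15}", l1))
  }
  if (length(second_seq) != l1) {
    violations <- c(violations, "sequences differ in length")
  }
  bad <- setdiff(first_seq, eligible_pool())
  if (length(bad)) {
    violations <- c(violations,
                    sprintf("inadmissible first-sequence numbers: %s",
                            paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(first_seq)) {
    violations <- c(violations, "duplicates in first sequence")
  }
  if (anyDuplicated(second_seq)) {
    violations <- c(violations, "duplicates in second sequence")
  }
  if (any(second_seq < 1 | second_seq > 99)) {
    violations <- c(violations, "second-sequence numbers outside 1-99")
  }
  overlap <- sum(first_seq %in% second_seq)
  implied_p <- overlap / l1
  if (!any(abs(implied_p - c(0, 1 / 5, 4 / 5, 1)) < 1e-12)) {
    violations <- c(violations,
                    sprintf("implied probability %d/%d is not a designed value",
                            overlap, l1))
  }
  list(implied_p = implied_p, overlap = overlap,
       valid = length(violations) == 0L, violations = violations)
}

#' Generate a full randomizer deployment sheet for a survey
#'
#' Produces, for every question and both sub-samples, an independently
#' generated sequence pair. The probabilities (1/5, 4/5) are assigned to
#' sub-samples (1, 2) for odd-numbered questions and reversed for
#' even-numbered ones, so each sub-sample sees alternating probabilities
#' while every question keeps the complementary pair. An optional control
#' item with `p` 0 or 1 (known-prevalence question) is appended, with the
#' same degenerate probability in both sub-samples.
#'
#' @param questions Character vector of question labels.
#' @param L Sequence length: 5, 10 or 15.
#' @param seed Optional integer seed.
#' @param control_p `NULL` for no control item, else 0 or 1.
#' @return A data frame with one row per question x sub-sample: `question`,
#'   `subsample`, `p`, `first_seq`, `second_seq` (sequences as
#'   space-separated strings, ready for a survey platform), plus the
#'   generated pairs in the `"pairs"` attribute.
#' @examples
#' design_survey(c("Q1", "Q2"), L = 5, seed = 1)
#' @export
design_survey <- function(questions, L, seed = NULL, control_p = NULL) {
  stopifnot(length(questions) >= 1L)
  if (!is.null(control_p) && !control_p %in% c(0, 1)) {
    stop("'control_p' must be 0 or 1", call. = FALSE)
  }
  with_seed(seed, {
    rows <- list()
    pairs <- list()
    add_item <- function(label, p_sub1) {
      for (sub in 1:2) {
        p <- if (sub == 1L) p_sub1 else 1 - p_sub1
        if (!is.null(control_p) && label == "control") p <- control_p
        pair <- generate_pair(L, p)
        key <- sprintf("%s.s%d", label, sub)
        pairs[[key]] <<- pair
        rows[[key]] <<- data.frame(
          question = label, subsample = sub, p = p,
          first_seq = paste(pair$first_seq, collapse = " "),
          second_seq = paste(pair$second_seq, collapse = " "))
      }
    }
    for (i in seq_along(questions)) {
      add_item(questions[i], if (i %% 2L == 1L) 1 / 5 else 4 / 5)
    }
    if (!is.null(control_p)) add_item("control", control_p)
    sheet <- do.call(rbind, rows)
    rownames(sheet) <- NULL
    attr(sheet, "pairs") <- pairs
    sheet
  })
}
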