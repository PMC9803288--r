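test_that("eligible pool is exactly the 72 memorable-safe two-digit numbers", {
  pool <- eligible_pool()
  expect_length(pool, 72)
  # brute-force enumeration oracle
  oracle <- setdiff(10:99, c(seq(11, 99, by = 11), seq(10, 90, by = 10)))
  expect_setequal(pool, oracle)
  expect_false(any(c(7, 10, 40, 44, 99) %in% pool))
  expect_true(all(c(12, 98, 21) %in% pool))
})

test_that("generated pairs hit the designed overlap exactly", {
  for (L in c(5L, 10L, 15L)) {
    for (p in c(0, 1 / 5, 4 / 5, 1)) {
      pair <- generate_pair(L, p, seed = L + round(100 * p))
      expect_length(pair$first_seq, L)
      expect_length(pair$second_seq, L)
      expect_identical(pair$overlap, as.integer(round(L * p)))
      # rational arithmetic: implied probability equals the target exactly
      expect_identical(pair$implied_p, p)
      expect_true(all(pair$first_seq %in% eligible_pool()))
      expect_identical(anyDuplicated(pair$first_seq), 0L)
      expect_identical(anyDuplicated(pair$second_seq), 0L)
      expect_true(all(pair$second_seq >= 1 & pair$second_seq <= 99))
    }
  }
  # the fixed-probability designs: overlaps {1,2,3} and {4,8,12}
  expect_identical(vapply(c(5L, 10L, 15L),
                          function(L) generate_pair(L, 1 / 5, seed = 1)$overlap,
                          integer(1)), c(1L, 2L, 3L))
  expect_identical(vapply(c(5L, 10L, 15L),
                          function(L) generate_pair(L, 4 / 5, seed = 1)$overlap,
                          integer(1)), c(4L, 8L, 12L))
})

test_that("control items reorder the full first sequence", {
  for (L in c(5L, 10L, 15L)) {
    pair <- generate_pair(L, 1, seed = L)
    expect_setequal(pair$second_seq, pair$first_seq)
    expect_false(identical(pair$second_seq, pair$first_seq))
    expect_identical(pair$implied_p, 1)
  }
  zero <- generate_pair(5, 0, seed = 9)
  expect_identical(zero$overlap, 0L)
  expect_length(intersect(zero$first_seq, zero$second_seq), 0)
})

test_that("generation is seed-deterministic and validation round-trips", {
  a <- generate_pair(10, 4 / 5, seed = 123)
  b <- generate_pair(10, 4 / 5, seed = 123)
  expect_identical(a, b)
  rep <- validate_pair(a)
  expect_true(rep$valid)
  expect_identical(rep$implied_p, 4 / 5)
  expect_length(rep$violations, 0)
  # tampered items are flagged
  bad <- a
  bad$first_seq[1] <- 44L
  expect_false(validate_pair(bad)$valid)
  expect_match(validate_pair(bad)$violations, "44", all = FALSE)
  expect_error(generate_pair(7, 1 / 5), "'L'")
  expect_error(generate_pair(10, 0.3), "target_p")
})

test_that("survey sheets alternate the probabilities between questions", {
  sheet <- design_survey(paste0("Q", 1:4), L = 10, seed = 5)
  s1 <- sheet[sheet$subsample == 1, ]
  expect_identical(s1$p[match(paste0("Q", 1:4), s1$question)],
                   c(1 / 5, 4 / 5, 1 / 5, 4 / 5))
  # complementary probabilities within every question
  for (q in paste0("Q", 1:4)) {
    expect_identical(sum(sheet$p[sheet$question == q]), 1)
  }
  # single question: the two sub-samples are complementary
  one <- design_survey("only", L = 5, seed = 6)
  expect_identical(sum(one$p), 1)
  # control item with p = 1 in both sub-samples, reordered sequences
  ctrl_sheet <- design_survey(c("Q1", "Q2"), L = 5, seed = 7, control_p = 1)
  ctrl <- ctrl_sheet[ctrl_sheet$question == "control", ]
  expect_identical(ctrl$p, c(1, 1))
  pairs <- attr(ctrl_sheet, "pairs")
  expect_setequal(pairs[["control.s1"]]$second_seq,
                  pairs[["control.s1"]]$first_seq)
  # all emitted items validate
  for (pair in attr(sheet, "pairs")) {
    expect_true(validate_pair(pair)$valid)
  }
})
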