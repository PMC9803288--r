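# counts object for one question of the bundled three-study dataset
fixture_counts <- function(label) {
  df <- three_studies()
  row <- df[df$label == label, , drop = FALSE]
  stopifnot(nrow(row) == 1L)
  crosswise_counts(row$n21, row$n11, row$n22, row$n12,
                   design = ecwm_design(row$p1, control = TRUE),
                   label = row$label)
}

# expected (non-integer) cell counts on the model manifold at prevalence pi
expected_counts <- function(pi, design, n1, n2, label = "expected") {
  design <- ecwm_design(design, control = TRUE)
  structure(
    list(label = label,
         n21 = n1 * response_prob(2, 1, pi, design),
         n11 = n1 * response_prob(1, 1, pi, design),
         n22 = n2 * response_prob(2, 2, pi, design),
         n12 = n2 * response_prob(1, 2, pi, design),
         design = design),
    class = "crosswise_counts")
}

# expected counts under informed self-protection (contaminated model)
expected_sp_counts <- function(pi, design, theta_c, theta_nc, n1, n2) {
  design <- ecwm_design(design)
  q <- sp_transition_matrix(design, theta_c, theta_nc)
  pr <- unname(drop(q %*% c(pi, 1 - pi)))
  structure(
    list(label = "expected_sp",
         n21 = n1 * pr[1], n11 = n1 * pr[2],
         n22 = n2 * pr[3], n12 = n2 * pr[4],
         design = design),
    class = "crosswise_counts")
}
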