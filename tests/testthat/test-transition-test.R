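two_state <- function(m) {
  transition_matrix(matrix(m, 2, byrow = TRUE,
                           dimnames = list(c("x", "y"), c("x", "y"))))
}

test_that("expected counts redistribute B's row totals under A's kernel", {
  A <- two_state(c(3, 7, 5, 5))
  B <- two_state(c(6, 4, 1, 1))
  E <- expected_transitions(A, B)
  expect_equal(unname(E["x", ]), c(3, 7)) # row total 10 x probs (0.3, 0.7)
  # row sums of E match B's observed row totals wherever A's row is defined
  expect_equal(rowSums(E), rowSums(B$counts))

  # B with an empty row yields a zero expectation row
  B0 <- two_state(c(6, 4, 0, 0))
  expect_equal(unname(expected_transitions(A, B0)["y", ]), c(0, 0))

  # self-consistency: A = B's own kernel reproduces B's counts exactly
  expect_equal(expected_transitions(B, B), matrix(as.numeric(B$counts), 2,
               dimnames = dimnames(B$counts)), ignore_attr = TRUE)

  bad <- transition_matrix(matrix(c(1, 1, 1, 1), 2,
                                  dimnames = list(c("p", "q"), c("p", "q"))))
  expect_error(expected_transitions(A, bad), "state order")
})

test_that("the chi-square score matches hand evaluation on toys", {
  A <- two_state(c(5, 5, 5, 5)) # uniform kernel
  B <- two_state(c(10, 0, 0, 10))
  E <- expected_transitions(A, B)
  sc <- chi_square_score(B, E)
  expect_equal(sc$C, 20) # 4 cells of (5)^2/5
  expect_equal(sc$cells_used, 4L)

  # B identical to expectation -> C = 0
  expect_equal(chi_square_score(B, matrix(as.numeric(B$counts), 2))$C, 0)

  # 3-state toy with a structurally zero column in A
  kA <- matrix(c(4, 4, 0, 2, 6, 0, 3, 5, 0), 3, byrow = TRUE,
               dimnames = list(c3, c3))
  kB <- matrix(c(5, 3, 1, 1, 7, 0, 4, 4, 0), 3, byrow = TRUE,
               dimnames = list(c3, c3))
  A3 <- transition_matrix(kA, c3)
  B3 <- transition_matrix(kB, c3)
  E3 <- expected_transitions(A3, B3)
  # brute force over all 9 cells, skipping zero expectations
  cbrute <- 0
  used <- 0L
  for (i in 1:3) for (j in 1:3) {
    if (E3[i, j] > 0) {
      cbrute <- cbrute + (kB[i, j] - E3[i, j])^2 / E3[i, j]
      used <- used + 1L
    }
  }
  sc3 <- chi_square_score(B3, E3)
  expect_equal(sc3$C, cbrute)
  expect_equal(sc3$cells_used, used)
  expect_equal(used, 6L) # the zero column of A is excluded everywhere
})

test_that("df bookkeeping and critical values are exact", {
  expect_identical(degrees_of_freedom(18, 18, 242), 64L)
  expect_identical(degrees_of_freedom(18, 18, 246), 60L)
  expect_identical(degrees_of_freedom(2, 2, 0), 2L)
  expect_error(degrees_of_freedom(2, 2, 2), "degenerate")

  expect_equal(round(chisq_critical_value(64, 0.001), 3), 104.716)
  expect_equal(round(chisq_critical_value(60, 0.001), 3), 99.607)
  # chi-square(1) median via an independent root-find on the CDF
  med <- uniroot(function(q) stats::pchisq(q, 1) - 0.5, c(0.1, 2),
                 tol = 1e-9)$root
  expect_equal(chisq_critical_value(1, 0.5), med, tolerance = 1e-6)
  expect_error(chisq_critical_value(0, 0.05), "df")
  expect_error(chisq_critical_value(5, 1.5), "alpha")
})

test_that("comparing a corpus with itself accepts the null with C = 0", {
  log <- simulate_corpus(n_sessions = 30, seed = 400)
  A <- transition_counts(dplyr::filter(log, group == "L1"))
  cmp <- compare_transition_matrices(A, A, alpha = 0.001)
  g <- glance(cmp)
  expect_equal(g$C, 0)
  expect_false(g$reject_null)
  expect_equal(g$K, 18L)
})

test_that("excluded-cell accounting partitions the K^2 cells", {
  log <- simulate_corpus(n_sessions = 40, seed = 401)
  A <- transition_counts(dplyr::filter(log, group == "L1"))
  B <- transition_counts(dplyr::filter(log, group == "L2"))
  td <- tidy(compare_transition_matrices(A, B))
  for (r in seq_len(nrow(td))) {
    row <- td[r, ]
    tested <- if (row$direction == "AB") B else A
    unocc_rows <- sum(rowSums(tested$counts) == 0)
    expect_equal(row$cells_used + row$N2 + unocc_rows * row$K, row$K^2)
    expect_equal(row$df, row$K^2 - row$N1 - row$N2)
  }
})

test_that("C is invariant under consistent state relabeling", {
  log <- simulate_corpus(n_sessions = 25, seed = 402)
  A <- transition_counts(dplyr::filter(log, group == "L1"))
  B <- transition_counts(dplyr::filter(log, group == "L3"))
  perm <- sample(seq_along(A$state_order))
  Ap <- transition_matrix(A$counts[perm, perm], A$state_order[perm])
  Bp <- transition_matrix(B$counts[perm, perm], B$state_order[perm])
  expect_equal(glance(compare_transition_matrices(Ap, Bp))$C,
               glance(compare_transition_matrices(A, B))$C)
})

test_that("scaling B's deviation from expectation never decreases C", {
  A3 <- transition_matrix(matrix(c(6, 2, 2, 2, 6, 2, 2, 2, 6), 3,
                                 byrow = TRUE, dimnames = list(c3, c3)), c3)
  # B = expectation + t * D where D preserves row totals
  E <- matrix(c(30, 10, 10, 10, 30, 10, 10, 10, 30), 3, byrow = TRUE,
              dimnames = list(c3, c3))
  D <- matrix(c(2, -1, -1, 0, 0, 0, -1, -1, 2), 3, byrow = TRUE)
  cs <- vapply(0:3, function(t) {
    Bt <- transition_matrix(E + t * D, c3)
    chi_square_score(Bt, expected_transitions(A3, Bt))$C
  }, numeric(1))
  expect_equal(cs[1], 0)
  expect_true(all(diff(cs) >= 0))
})

test_that("compare_groups wires group labels through to the decision", {
  log <- simulate_corpus(n_sessions = 200, seed = 403)
  cmp <- compare_groups(log, "L1", "L3", alpha = 0.001)
  g <- glance(cmp)
  expect_true(g$reject_null) # well-separated kernels at this size
  expect_setequal(tidy(cmp)$direction, c("AB", "BA"))
  expect_equal(cmp$labels, c("L1", "L3"))
  expect_error(compare_groups(log, "L1", "L9"), "L9")
})
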