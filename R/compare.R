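# Chi-square comparison of two first-order transition matrices.
#
# The procedure treats one sample (A) as the reference: expected counts for
# the tested sample (B) are B's row totals redistributed under A's transition
# kernel, E_ij = n_i(B) * p_ij(A), and the Pearson-type score
# C = sum (f_ij(B) - E_ij)^2 / E_ij over cells with positive expectation is
# referred to a chi-square distribution with df = K^2 - N1 - N2, where K is
# the size of the state space, N1 the number of states actually occurring in
# B and N2 the number of impossible transitions (cells excluded for zero
# expectation in rows B occupies). Cells in rows B never occupies contribute
# nothing and are not counted in N2.

#' Expected transition counts for sample B under sample A's kernel
#'
#' @param A,B `transition_matrix` objects sharing the same `state_order`.
#' @return A K x K numeric matrix `E` with `E[i, j]` = (B's row-i total) x
#'   (A's row-i probability of j). Rows where A has zero total produce zero
#'   expectations; their names are attached as attribute `undefined_rows`.
#' @examples
#' a <- transition_matrix(matrix(c(3, 7, 5, 5), 2, byrow = TRUE,
#'                               dimnames = list(c("x", "y"), c("x", "y"))))
#' b <- transition_matrix(matrix(c(10, 0, 0, 10), 2, byrow = TRUE,
#'                               dimnames = list(c("x", "y"), c("x", "y"))))
#' expected_transitions(a, b)
#' @export
expected_transitions <- function(A, B) {
  stopifnot(inherits(A, "transition_matrix"), inherits(B, "transition_matrix"))
  if (!identical(A$state_order, B$state_order)) {
    stop("A and B must share the same state order")
  }
  E <- rowSums(B$counts) * A$probabilities
  dimnames(E) <- dimnames(B$counts)
  undef <- A$state_order[rowSums(A$counts) == 0 & rowSums(B$counts) > 0]
  attr(E, "undefined_rows") <- undef
  E
}

#' Pearson chi-square score of observed vs expected transition counts
#'
#' @param B A `transition_matrix` (the tested sample).
#' @param E Expected count matrix from [expected_transitions()].
#' @return A list with `C` (the score, summed over cells with `E > 0`) and
#'   `cells_used` (how many cells entered the sum).
#' @export
chi_square_score <- function(B, E) {
  stopifnot(inherits(B, "transition_matrix"), all(dim(E) == dim(B$counts)))
  use <- E > 0
  list(
    C = sum((B$counts[use] - E[use])^2 / E[use]),
    cells_used = sum(use)
  )
}

#' Degrees of freedom for the transition-matrix comparison
#'
#' @param K Number of states in the state space.
#' @param N1 Number of actual states in the tested sample.
#' @param N2 Number of impossible transitions (excluded cells).
#' @return The integer `K^2 - N1 - N2`.
#' @examples
#' degrees_of_freedom(18, 18, 242) # 64
#' @export
degrees_of_freedom <- function(K, N1, N2) {
  K <- as.integer(K)
  df <- K * K - as.integer(N1) - as.integer(N2)
  if (df < 1) {
    stop("degenerate comparison: K^2 - N1 - N2 = ", df, " (< 1)")
  }
  df
}

#' Upper-tail chi-square critical value
#'
#' @param df Degrees of freedom (>= 1).
#' @param alpha Upper-tail probability in (0, 1).
#' @return The quantile `q` with `P(X > q) = alpha` for `X ~ chi-square(df)`.
#' @examples
#' round(chisq_critical_value(64, 0.001), 3) # 104.716
#' @export
chisq_critical_value <- function(df, alpha) {
  if (!is.numeric(df) || df < 1) stop("df must be >= 1")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  stats::qchisq(alpha, df = df, lower.tail = FALSE)
}

# Internal: one direction of the comparison (A reference, B tested).
.compare_one <- function(A, B, alpha) {
  K <- length(B$state_order)
  E <- expected_transitions(A, B)
  occ <- rowSums(B$counts) > 0
  # actual states in B: appear as source or destination of some transition
  N1 <- sum(occ | colSums(B$counts) > 0)
  # impossible transitions: zero-expectation cells within occupied rows
  N2 <- sum(E[occ, , drop = FALSE] == 0)
  sc <- chi_square_score(B, E)
  df <- degrees_of_freedom(K, N1, N2)
  crit <- chisq_critical_value(df, alpha)
  tibble::tibble(
    C = sc$C, K = K, N1 = N1, N2 = N2, df = df,
    alpha = alpha, critical_value = crit,
    reject_null = sc$C > crit, cells_used = sc$cells_used
  )
}

#' Compare two transition matrices with the chi-square procedure
#'
#' Tests the null hypothesis that two samples of activity sequences share the
#' same first-order transition probability matrix. The procedure is
#' directional (one sample is the reference whose kernel generates the
#' expected counts for the other); both directions are computed, and the
#' reported decision uses the direction with the larger score unless a single
#' direction is requested. The chi-square reference distribution is reliable
#' when the reference sample is large relative to the tested one (its kernel
#' is treated as known); see the package vignette.
#'
#' @param A,B `transition_matrix` objects on the same state order.
#' @param alpha Significance level for the upper-tail critical value.
#'   Default 0.001.
#' @param direction `"both"` (default; report the max-C direction),
#'   `"AB"` (A reference, B tested) or `"BA"`.
#' @param labels Length-2 character vector naming A and B in the output.
#' @return A `transition_comparison` object; see [tidy.transition_comparison()]
#'   and [glance.transition_comparison()].
#' @examples
#' log <- simulate_corpus(n_sessions = 50, seed = 1)
#' tms <- group_transition_matrices(log)
#' compare_transition_matrices(tms$L1, tms$L3)
#' @export
compare_transition_matrices <- function(A, B, alpha = 0.001,
                                        direction = c("both", "AB", "BA"),
                                        labels = c("A", "B")) {
  direction <- match.arg(direction)
  res <- list()
  if (direction %in% c("both", "AB")) {
    res$AB <- dplyr::mutate(
      .compare_one(A, B, alpha),
      direction = "AB", reference = labels[[1]], tested = labels[[2]],
      .before = 1
    )
  }
  if (direction %in% c("both", "BA")) {
    res$BA <- dplyr::mutate(
      .compare_one(B, A, alpha),
      direction = "BA", reference = labels[[2]], tested = labels[[1]],
      .before = 1
    )
  }
  res <- dplyr::bind_rows(res)
  reported <- res$direction[[which.max(res$C)]]
  structure(
    list(directions = res, reported = reported, labels = labels, alpha = alpha),
    class = "transition_comparison"
  )
}

#' Compare two familiarity groups from a labeled session log
#'
#' Convenience wrapper: builds the two groups' transition matrices from a
#' labeled session log and runs [compare_transition_matrices()].
#'
#' @param sessions Labeled session log tibble.
#' @param group_a,group_b Group labels present in `sessions$group`.
#' @inheritParams compare_transition_matrices
#' @return A `transition_comparison` object.
#' @export
compare_groups <- function(sessions, group_a, group_b, alpha = 0.001,
                           direction = c("both", "AB", "BA")) {
  for (g in c(group_a, group_b)) {
    if (!g %in% sessions$group) stop("no sessions labeled ", g)
  }
  A <- transition_counts(dplyr::filter(sessions, .data$group == group_a))
  B <- transition_counts(dplyr::filter(sessions, .data$group == group_b))
  compare_transition_matrices(A, B, alpha = alpha, direction = direction,
                              labels = c(group_a, group_b))
}

#' @export
print.transition_comparison <- function(x, ...) {
  g <- glance.transition_comparison(x)
  cat("Chi-square comparison of transition matrices (", x$labels[[1]], " vs ",
      x$labels[[2]], ")\n", sep = "")
  cat(sprintf(
    "  C = %.3f on df = %d (K^2 = %d, N1 = %d, N2 = %d)\n",
    g$C, g$df, g$K^2, g$N1, g$N2
  ))
  cat(sprintf(
    "  critical value %.3f at alpha = %g -> %s H0 (direction %s: %s tested against %s)\n",
    g$critical_value, g$alpha,
    if (g$reject_null) "reject" else "retain",
    g$direction, g$tested, g$reference
  ))
  invisible(x)
}

#' Tidy a transition-matrix comparison
#'
#' @param x A `transition_comparison`.
#' @param ... Unused.
#' @return A tibble with one row per computed direction: `direction`,
#'   `reference`, `tested`, `C`, `K`, `N1`, `N2`, `df`, `alpha`,
#'   `critical_value`, `reject_null`, `cells_used`.
#' @export
tidy.transition_comparison <- function(x, ...) {
  x$directions
}

#' One-row summary of a transition-matrix comparison (reported direction)
#'
#' @inheritParams tidy.transition_comparison
#' @return One-row tibble for the direction with the larger C.
#' @export
glance.transition_comparison <- function(x, ...) {
  dplyr::filter(x$directions, .data$direction == x$reported)
}
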