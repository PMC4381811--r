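# First-order Markov transition matrices over the activity alphabet.

#' Construct a transition matrix object
#'
#' Low-level constructor wrapping an 18x18 (or K x K) table of first-order
#' transition counts into a `transition_matrix` object with row-normalised
#' probabilities. Most users will call [transition_counts()] on a session log
#' instead; the constructor is useful for injecting published count tables.
#'
#' @param counts Square numeric matrix of nonnegative transition counts with
#'   matching row/column names, or an unnamed matrix plus `state_order`.
#' @param state_order Character vector of state names fixing the row/column
#'   order; defaults to the matrix dimnames or the 18-code alphabet.
#' @param n_sessions Optional number of contributing sessions (metadata).
#' @return A `transition_matrix`: list with `counts`, `probabilities`
#'   (rows with zero total stay all-zero), `state_order`, `total_transitions`
#'   and `n_sessions`.
#' @export
transition_matrix <- function(counts, state_order = NULL, n_sessions = NA_integer_) {
  counts <- as.matrix(counts)
  if (is.null(state_order)) {
    state_order <- rownames(counts)
    if (is.null(state_order)) state_order <- .activity_codes
  }
  K <- length(state_order)
  if (!all(dim(counts) == K)) {
    stop("counts must be a ", K, "x", K, " matrix matching state_order")
  }
  dimnames(counts) <- list(from = state_order, to = state_order)
  if (any(counts < 0)) stop("transition counts must be nonnegative")
  rt <- rowSums(counts)
  probs <- counts / ifelse(rt > 0, rt, 1)
  structure(
    list(
      counts = counts,
      probabilities = probs,
      state_order = state_order,
      total_transitions = sum(counts),
      n_sessions = n_sessions
    ),
    class = "transition_matrix"
  )
}

#' Estimate first-order transition counts from a session log
#'
#' Tallies every within-session move from one activity to the next into a
#' K x K count matrix over the fixed 18-code state space, and row-normalises
#' to a first-order Markov transition probability matrix. Transitions never
#' cross session boundaries, so a session of length L contributes L - 1
#' transitions.
#'
#' @param sessions A session log tibble (one familiarity group, or any set of
#'   sessions to pool). Use [group_transition_matrices()] for a labeled,
#'   multi-group log.
#' @param state_order State order for rows/columns; default the 18 codes.
#' @return A `transition_matrix` object (see [transition_matrix()]).
#' @examples
#' log <- sessions_tbl(list(c("Q:AccSE", "Q:NewQ", "E:ExamSR")))
#' transition_counts(log)$total_transitions # 2
#' @export
transition_counts <- function(sessions, state_order = .activity_codes) {
  sessions <- .qualify_sessions(sessions)
  seqs <- .session_seqs(sessions)
  from <- unlist(lapply(seqs, function(s) s[-length(s)]), use.names = FALSE)
  to <- unlist(lapply(seqs, function(s) s[-1]), use.names = FALSE)
  if (length(from) == 0) {
    stop("no transitions: every session has length < 2")
  }
  counts <- table(
    factor(from, levels = state_order),
    factor(to, levels = state_order)
  )
  counts <- matrix(as.integer(counts), nrow = length(state_order),
                   dimnames = list(from = state_order, to = state_order))
  transition_matrix(counts, state_order, n_sessions = length(seqs))
}

#' Per-group transition matrices
#'
#' @param sessions A labeled session log tibble.
#' @return Named list of `transition_matrix` objects, one per group label.
#' @export
group_transition_matrices <- function(sessions) {
  if (!"group" %in% names(sessions) || anyNA(sessions$group)) {
    stop("all sessions must carry a familiarity group label")
  }
  sessions |>
    dplyr::group_split(.data$group) |>
    stats::setNames(sort(unique(sessions$group))) |>
    purrr::map(transition_counts)
}

#' Most frequent transitions in a group
#'
#' Ranks the cells of a transition count matrix by descending frequency and
#' reports each as a share of the group's total transitions, together with
#' the cumulative frequency and share of the top k. Ties are broken by
#' (from, to) lexicographic order on the canonical code strings so reports
#' are deterministic.
#'
#' @param tm A `transition_matrix`.
#' @param k Number of transitions to report (default 10).
#' @return A tibble `rank`, `from`, `to`, `n`, `share_pct` with attributes
#'   `cum_n`, `cum_share_pct` and `total_transitions`.
#' @examples
#' log <- simulate_corpus(n_sessions = 30, seed = 1)
#' tms <- group_transition_matrices(log)
#' top_transitions(tms$L1, k = 10)
#' @export
top_transitions <- function(tm, k = 10) {
  stopifnot(inherits(tm, "transition_matrix"), k >= 1)
  long <- tidy.transition_matrix(tm) |>
    dplyr::filter(.data$n > 0) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$from, .data$to) |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      share_pct = 100 * .data$n / tm$total_transitions
    ) |>
    dplyr::select("rank", "from", "to", "n", "share_pct")
  out <- utils::head(long, k)
  attr(out, "cum_n") <- sum(out$n)
  attr(out, "cum_share_pct") <- 100 * sum(out$n) / tm$total_transitions
  attr(out, "total_transitions") <- tm$total_transitions
  out
}

#' Mean and SD of observed transition counts
#'
#' Summarises the multiset of counts over ordered state pairs observed at
#' least once: on average, how often was each distinct transition performed.
#' The standard deviation uses the population denominator (n), recorded in
#' the `sd_denominator` column; the analogous sample-denominator value is
#' `sd * sqrt(n_cells / (n_cells - 1))`.
#'
#' @param tm A `transition_matrix`.
#' @return One-row tibble: `n_cells`, `mean`, `sd`, `sd_denominator`.
#' @export
mean_transition_stats <- function(tm) {
  stopifnot(inherits(tm, "transition_matrix"))
  x <- tm$counts[tm$counts > 0]
  m <- mean(x)
  tibble::tibble(
    n_cells = length(x),
    mean = m,
    sd = sqrt(mean((x - m)^2)),
    sd_denominator = "population"
  )
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("First-order transition matrix:", length(x$state_order), "states,",
      x$total_transitions, "transitions",
      if (!is.na(x$n_sessions)) paste0("(", x$n_sessions, " sessions)"), "\n")
  obs <- sum(x$counts > 0)
  cat("Observed ordered pairs:", obs, "of", length(x$state_order)^2, "\n")
  invisible(x)
}

#' Tidy a transition matrix into long format
#'
#' @param x A `transition_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `from`, `to`, `n`, `p` (row-conditional
#'   probability).
#' @export
tidy.transition_matrix <- function(x, ...) {
  K <- length(x$state_order)
  tibble::tibble(
    from = rep(x$state_order, each = K),
    to = rep(x$state_order, times = K),
    n = as.vector(t(x$counts)),
    p = as.vector(t(x$probabilities))
  )
}

#' @export
glance.transition_matrix <- function(x, ...) {
  tibble::tibble(
    states = length(x$state_order),
    total_transitions = x$total_transitions,
    observed_cells = sum(x$counts > 0),
    n_sessions = x$n_sessions
  )
}

#' Write a transition matrix as CSV (counts) with code header row/column
#'
#' @param tm A `transition_matrix`.
#' @param path Output file path.
#' @param what `"counts"` (default) or `"probabilities"`.
#' @export
write_transition_matrix <- function(tm, path, what = c("counts", "probabilities")) {
  what <- match.arg(what)
  m <- tm[[what]]
  df <- data.frame(from = rownames(m), m, check.names = FALSE)
  readr::write_csv(df, path)
  invisible(path)
}
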