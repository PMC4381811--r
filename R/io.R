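# Readers/writers for session logs and questionnaires, and the end-to-end
# pipeline runner.

#' Read a session log from CSV or JSON
#'
#' The CSV layout has one row per activity with header columns
#' `participant_id`, `topic_id`, `step`, `activity_code` (an optional `group`
#' column is preserved). The JSON layout is a list of session objects, each
#' with `participant_id`, `topic_id`, optionally `group`, and an `activities`
#' array. Sessions failing validation (unknown codes, broken step numbering)
#' are excluded with a warning and reported in the `excluded` attribute,
#' so only qualified sessions enter the analysis.
#'
#' @param path Path to a `.csv` or `.json` file.
#' @return A session log tibble with attribute `excluded` (violations tibble).
#' @export
read_sessions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    log <- purrr::map_dfr(raw, function(s) {
      tibble::tibble(
        participant_id = as.character(s$participant_id),
        topic_id = as.integer(s$topic_id),
        group = if (!is.null(s$group)) as.character(s$group) else NA_character_,
        step = seq_along(s$activities),
        activity = as.character(unlist(s$activities))
      )
    })
  } else {
    log <- readr::read_csv(path, show_col_types = FALSE)
    req <- c("participant_id", "topic_id", "step", "activity_code")
    miss <- setdiff(req, names(log))
    if (length(miss) > 0) {
      stop("session CSV is missing columns: ", paste(miss, collapse = ", "))
    }
    log <- log |>
      dplyr::rename(activity = "activity_code") |>
      dplyr::mutate(
        participant_id = as.character(.data$participant_id),
        topic_id = as.integer(.data$topic_id),
        step = as.integer(.data$step)
      )
    if (!"group" %in% names(log)) log$group <- NA_character_
  }
  log <- dplyr::mutate(
    log,
    session_id = paste0(.data$participant_id, ".", .data$topic_id),
    .before = 1
  )
  v <- validate_sessions(log)
  out <- .qualify_sessions(log)
  attr(out, "excluded") <- v
  out
}

#' Write a session log to CSV or JSON
#'
#' @param sessions Session log tibble.
#' @param path Output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    seqs <- .session_seqs(sessions)
    meta <- dplyr::distinct(
      sessions, .data$session_id, .data$participant_id,
      .data$topic_id, group = .data$group
    )
    objs <- purrr::map(meta$session_id, function(id) {
      row <- meta[meta$session_id == id, ]
      list(
        participant_id = row$participant_id, topic_id = row$topic_id,
        group = row$group, activities = seqs[[id]]
      )
    })
    jsonlite::write_json(objs, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    sessions |>
      dplyr::select(
        "participant_id", "topic_id",
        dplyr::any_of("group"), "step", activity_code = "activity"
      ) |>
      readr::write_csv(path)
  }
  invisible(path)
}

#' Read a questionnaire response table from CSV
#'
#' Expected columns: `participant_id`, `section`, `topic_id`, `item_index`,
#' `status` with status vocabulary `correct` / `incorrect` / `unknown`.
#'
#' @param path Path to a CSV file.
#' @return A questionnaire response tibble.
#' @export
read_questionnaire <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  resp <- readr::read_csv(path, show_col_types = FALSE) |>
    dplyr::mutate(
      participant_id = as.character(.data$participant_id),
      section = as.integer(.data$section),
      topic_id = as.integer(.data$topic_id),
      item_index = as.integer(.data$item_index)
    )
  .check_response_cols(resp)
  resp
}

#' Run the full search-behaviour analysis pipeline
#'
#' Executes the analysis stages in their natural order on a labeled session
#' log (labels can alternatively be derived from a questionnaire table):
#' activity frequencies, per-group transition matrices and ranked transition
#' reports, pairwise chi-square comparisons of groups, n-gram order
#' selection by held-out perplexity (per group and pooled), top-k frequent
#' patterns with behavioural categories at the selected order, and search
#' efficiency. A manifest records the seed and configuration.
#'
#' @param sessions Session log tibble. If it carries no `group` labels,
#'   `questionnaire` must be supplied and labels are joined by participant
#'   and topic.
#' @param questionnaire Optional questionnaire response tibble.
#' @param alpha Significance level for group comparisons (default 0.001).
#' @param orders Candidate n-gram orders (default 2:7).
#' @param fraction Training fraction for the perplexity split.
#' @param top_k Depth of ranked transition/pattern reports.
#' @param seed Seed for the train/test split.
#' @return A `seekr_pipeline` list: `frequencies`, `efficiency`,
#'   `transition_matrices`, `top_transitions`, `comparisons`,
#'   `order_selection`, `patterns`, `scores` (when labeled from a
#'   questionnaire) and `manifest`.
#' @examples
#' log <- simulate_corpus(n_sessions = 30, seed = 1)
#' res <- run_pipeline(log, orders = 2:3, seed = 1)
#' names(res)
#' @export
run_pipeline <- function(sessions, questionnaire = NULL, alpha = 0.001,
                         orders = 2:7, fraction = 0.8, top_k = 20,
                         seed = 1L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  scores <- NULL
  if (!is.null(questionnaire)) {
    scores <- stage("familiarity labeling", score_familiarity(questionnaire))
    sessions <- sessions |>
      dplyr::select(-dplyr::any_of("group")) |>
      dplyr::left_join(
        dplyr::select(scores, "participant_id", "topic_id", group = "label"),
        by = c("participant_id", "topic_id")
      )
  }
  if (!"group" %in% names(sessions) || anyNA(sessions$group)) {
    stop("sessions are not fully labeled; supply a questionnaire or group column")
  }
  sessions <- stage("validation", .qualify_sessions(sessions))
  freqs <- stage("frequencies", activity_frequencies(sessions))
  eff <- stage("efficiency", search_efficiency(sessions))
  tms <- stage("transitions", group_transition_matrices(sessions))
  tops <- purrr::map(tms, top_transitions, k = top_k)
  groups <- names(tms)
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  comparisons <- stage("chi-square comparisons", purrr::map(pairs, function(pr) {
    compare_groups(sessions, pr[[1]], pr[[2]], alpha = alpha)
  }) |> stats::setNames(purrr::map_chr(pairs, paste, collapse = "-")))
  sel <- stage("order selection", {
    per_group <- purrr::map(
      stats::setNames(groups, groups),
      function(g) select_order(dplyr::filter(sessions, .data$group == g),
                               orders = orders, fraction = fraction, seed = seed)
    )
    per_group$all <- select_order(sessions, orders = orders,
                                  fraction = fraction, seed = seed)
    per_group
  })
  best_n <- sel$all$best_order
  pats <- stage("patterns", pattern_summary(sessions, n = best_n, k = top_k))
  structure(
    list(
      scores = scores, frequencies = freqs, efficiency = eff,
      transition_matrices = tms, top_transitions = tops,
      comparisons = comparisons, order_selection = sel, patterns = pats,
      manifest = list(
        seed = seed, alpha = alpha, orders = orders, fraction = fraction,
        top_k = top_k, pattern_length = best_n,
        n_sessions = dplyr::n_distinct(sessions$session_id),
        n_activities = nrow(sessions),
        package_version = as.character(utils::packageVersion("seekr"))
      )
    ),
    class = "seekr_pipeline"
  )
}

#' @export
print.seekr_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("Search-behaviour pipeline:", m$n_sessions, "sessions /",
      m$n_activities, "activities\n")
  cat("Groups:", paste(names(x$transition_matrices), collapse = ", "), "\n")
  cat("Selected n-gram order:", m$pattern_length,
      "| alpha =", m$alpha, "| seed =", m$seed, "\n")
  for (cmp in x$comparisons) print(cmp)
  invisible(x)
}
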