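# Descriptive statistics of search activities per familiarity group.

.use_codes <- c("U:UseHI", "U:UseGI")
.access_codes <- c("A:SelHI", "A:SelGI", "A:XplorF", "A:AccB")

#' Activity frequency table per familiarity group
#'
#' Counts every activity code within each familiarity group and expresses it
#' as a share of that group's total activities. This is the per-group
#' activity-mix profile used to characterise how searchers in each
#' familiarity level distribute effort over the querying, accessing,
#' evaluating, using and discarding stages.
#'
#' @param sessions A labeled session log tibble; every session must carry a
#'   non-missing `group` label.
#' @param all_codes If `TRUE` (default), include zero rows for codes a group
#'   never performed, so every group has 18 rows.
#' @return A tibble with columns `group`, `code`, `stage`, `n` and `share`
#'   (fraction of the group's activities; shares within a group sum to 1).
#' @examples
#' log <- simulate_corpus(n_sessions = 5, seed = 1)
#' activity_frequencies(log)
#' @export
activity_frequencies <- function(sessions, all_codes = TRUE) {
  sessions <- .qualify_sessions(sessions)
  if (!"group" %in% names(sessions) || anyNA(sessions$group)) {
    stop("all sessions must carry a familiarity group label")
  }
  counts <- sessions |>
    dplyr::count(.data$group, code = .data$activity)
  if (all_codes) {
    counts <- counts |>
      tidyr::complete(
        group = unique(sessions$group),
        code = .activity_codes,
        fill = list(n = 0L)
      )
  }
  counts |>
    dplyr::mutate(code = factor(.data$code, levels = .activity_codes)) |>
    dplyr::arrange(.data$group, .data$code) |>
    dplyr::mutate(code = as.character(.data$code)) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(share = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(stage = activity_stage(.data$code), .after = "code")
}

#' Search efficiency of a familiarity group
#'
#' Search efficiency is the ratio of information-use activities
#' (`U:UseHI` + `U:UseGI`) to item-access activities
#' (`A:SelHI` + `A:SelGI` + `A:XplorF` + `A:AccB`): out of every item a
#' group opened, how many ended up being used as a relevant source.
#'
#' @param sessions A session log tibble. If a `group` column with labels is
#'   present, efficiency is computed per group; otherwise over the whole log.
#' @return A tibble with columns `group` (absent for unlabeled input),
#'   `n_use`, `n_access` and `efficiency`.
#' @examples
#' log <- simulate_corpus(n_sessions = 20, seed = 1)
#' search_efficiency(log)
#' @export
search_efficiency <- function(sessions) {
  sessions <- .qualify_sessions(sessions)
  grouped <- "group" %in% names(sessions) && !anyNA(sessions$group)
  if (grouped) sessions <- dplyr::group_by(sessions, .data$group)
  out <- sessions |>
    dplyr::summarise(
      n_use = sum(.data$activity %in% .use_codes),
      n_access = sum(.data$activity %in% .access_codes),
      .groups = "drop"
    ) |>
    dplyr::mutate(efficiency = .data$n_use / .data$n_access)
  if (any(out$n_access == 0)) {
    stop("search efficiency is undefined: a group has no accessing-stage activities")
  }
  out
}
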