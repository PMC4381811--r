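# Scoring of the 24-item health terminology familiarity questionnaire.
#
# The questionnaire has three sections covering the same four health topics,
# with two items per section x topic (six items per topic, 24 in total).
# Section 1 probes surface recognition of a term; sections 2 and 3 probe
# conceptual understanding of consumer-friendly and advanced terminology.
# A correct answer earns 0.15 points in section 1 and 0.175 in sections 2-3,
# so the per-topic maximum is 2*0.15 + 4*0.175 = 1.
#
# Points are multiples of 0.005; internally they are held as integers on a
# 1/200 scale so the L1/L2 threshold comparisons at 0.3 and 0.65 are exact.

.status_levels <- c("correct", "incorrect", "unknown")
.pts_int <- c(`1` = 30L, `2` = 35L, `3` = 35L) # per correct item, /200
.thr_l1 <- 60L   # 0.3  * 200
.thr_l2 <- 130L  # 0.65 * 200

.label_from_points_int <- function(p) {
  dplyr::case_when(p <= .thr_l1 ~ "L1", p <= .thr_l2 ~ "L2", TRUE ~ "L3")
}

.check_response_cols <- function(responses) {
  req <- c("participant_id", "section", "topic_id", "item_index", "status")
  miss <- setdiff(req, names(responses))
  if (length(miss) > 0) {
    stop("questionnaire table is missing columns: ", paste(miss, collapse = ", "))
  }
  bad <- setdiff(unique(responses$status), .status_levels)
  if (length(bad) > 0) {
    stop("unknown response status: ", paste(bad, collapse = ", "))
  }
  invisible(responses)
}

# Internal: validate that each participant x topic has exactly 2 items per
# section; returns a tibble of offending slots.
.missing_slots <- function(responses) {
  responses |>
    dplyr::count(.data$participant_id, .data$topic_id, .data$section) |>
    tidyr::complete(
      participant_id = unique(responses$participant_id),
      topic_id = unique(responses$topic_id),
      section = 1:3,
      fill = list(n = 0L)
    ) |>
    dplyr::filter(.data$n != 2L)
}

#' Score one participant's questionnaire responses for one topic
#'
#' Scores the six items (two per section) a participant answered for a single
#' health topic and assigns the familiarity label: L1 (unfamiliar) for total
#' points \eqn{\le 0.3}, L2 (somewhat familiar) for points in (0.3, 0.65],
#' and L3 (familiar) above 0.65. An `"unknown"` response scores the same as
#' an incorrect one: participants are instructed not to guess, and points are
#' only ever awarded for correct answers.
#'
#' @param responses A tibble with columns `participant_id`, `section` (1-3),
#'   `topic_id`, `item_index` (1-2) and `status`
#'   (`"correct"`, `"incorrect"`, `"unknown"`), for one participant x topic.
#' @return A one-row tibble: `participant_id`, `topic_id`, `points`, `label`.
#' @examples
#' resp <- tibble::tibble(
#'   participant_id = "p1", topic_id = 1L,
#'   section = rep(1:3, each = 2), item_index = rep(1:2, 3),
#'   status = c("correct", "correct", rep("incorrect", 4))
#' )
#' score_topic(resp) # boundary case: 0.3 points, still L1
#' @export
score_topic <- function(responses) {
  .check_response_cols(responses)
  if (dplyr::n_distinct(responses$participant_id) != 1 ||
      dplyr::n_distinct(responses$topic_id) != 1) {
    stop("score_topic() expects responses for exactly one participant and topic")
  }
  slots <- with(responses, paste(section, item_index))
  expected <- with(expand.grid(item = 1:2, sec = 1:3), paste(sec, item))
  if (anyDuplicated(slots) || !setequal(slots, expected) ||
      length(slots) != 6) {
    bad <- c(setdiff(expected, slots), slots[duplicated(slots)])
    stop("expected exactly two items per section (1-3); problem at (section item): ",
         paste(unique(bad), collapse = ", "))
  }
  pts <- sum(.pts_int[as.character(responses$section)] *
               (responses$status == "correct"))
  tibble::tibble(
    participant_id = responses$participant_id[[1]],
    topic_id = responses$topic_id[[1]],
    points = pts / 200,
    label = .label_from_points_int(pts)
  )
}

#' Score a full questionnaire table into familiarity labels
#'
#' Applies [score_topic()] to every participant x topic. Each participant
#' must have a complete questionnaire (24 items: two per section per topic);
#' incomplete questionnaires are rejected rather than imputed.
#'
#' @param responses Questionnaire tibble (see [score_topic()]) covering one
#'   or more participants.
#' @return A tibble with one row per participant x topic: `participant_id`,
#'   `topic_id`, `points`, `label`.
#' @examples
#' labels <- c(p1 = "L3", p2 = "L1")
#' resp <- simulate_questionnaire(labels, seed = 1)
#' score_familiarity(resp)
#' @export
score_familiarity <- function(responses) {
  .check_response_cols(responses)
  miss <- .missing_slots(responses)
  if (nrow(miss) > 0) {
    stop("incomplete questionnaire; slots with != 2 items (participant topic section): ",
         paste(utils::head(
           with(miss, paste0(participant_id, " t", topic_id, " s", section)), 8
         ), collapse = ", "))
  }
  responses |>
    dplyr::group_by(.data$participant_id, .data$topic_id) |>
    dplyr::group_split() |>
    purrr::map_dfr(score_topic) |>
    dplyr::arrange(.data$participant_id, .data$topic_id)
}

#' Familiarity label counts per health topic
#'
#' Tallies how many participants fall in each familiarity group for each
#' topic, with an optional grand-total row.
#'
#' @param scores Output of [score_familiarity()].
#' @param totals Add a `"Total"` row summing over topics (default `TRUE`).
#' @return A tibble with columns `topic_id`, `L1`, `L2`, `L3`, `n`.
#' @examples
#' resp <- simulate_questionnaire(c(p1 = "L2", p2 = "L2"), seed = 1)
#' familiarity_group_counts(score_familiarity(resp))
#' @export
familiarity_group_counts <- function(scores, totals = TRUE) {
  if (nrow(scores) == 0) {
    return(tibble::tibble(topic_id = character(), L1 = integer(),
                          L2 = integer(), L3 = integer(), n = integer()))
  }
  out <- scores |>
    dplyr::count(topic_id = as.character(.data$topic_id), .data$label) |>
    tidyr::complete(
      topic_id = unique(as.character(scores$topic_id)),
      label = c("L1", "L2", "L3"), fill = list(n = 0L)
    ) |>
    tidyr::pivot_wider(names_from = "label", values_from = "n") |>
    dplyr::mutate(n = .data$L1 + .data$L2 + .data$L3)
  if (totals && nrow(out) > 0) {
    tot <- dplyr::summarise(
      out, topic_id = "Total",
      dplyr::across(c("L1", "L2", "L3", "n"), sum)
    )
    out <- dplyr::bind_rows(out, tot)
  }
  out
}
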