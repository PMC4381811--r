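# Fixed 18-code activity alphabet and session validation.

# Canonical code order: querying, accessing, evaluating, using, discarding.
.activity_codes <- c(
  "Q:AccSE", "Q:AccHW", "Q:NewQ", "Q:ModQ",
  "A:SelHI", "A:SelGI", "A:XplorF", "A:AccB",
  "E:ExamSR", "E:DisSR", "E:EvalI", "E:FindQ",
  "U:UseHI", "U:UseGI",
  "D:DisHI", "D:DisGI", "D:UnchkHI", "D:UnchkGI"
)

.activity_stages <- c(
  rep("Querying", 4), rep("Accessing", 4), rep("Evaluating", 4),
  rep("Using", 2), rep("Discarding", 4)
)
names(.activity_stages) <- .activity_codes

.stage_levels <- c("Querying", "Accessing", "Evaluating", "Using", "Discarding")

# Boundary markers used by the n-gram module; never valid session activities.
.BOS <- "<s>"
.EOS <- "</s>"

#' The search activity coding scheme
#'
#' The fixed alphabet of 18 search activity codes used to transcribe health
#' information search sessions, grouped into five stages: querying (accessing
#' a search engine or health website, issuing or modifying a query), accessing
#' (selecting retrieved items, exploring forward, going back), evaluating
#' (examining or discarding result lists, evaluating a selected page, finding
#' a keyword on a page), using (assessing a health or general page as a
#' relevant source), and discarding (assessing a page as irrelevant, or
#' discarding it unvisited).
#'
#' Codes are canonical uppercase strings with a stage prefix and colon
#' (e.g. `"E:EvalI"`); all functions in the package reject near-miss
#' spellings rather than normalising them, so corpora stay auditable.
#'
#' @return A tibble with columns `code` (character, 18 values) and `stage`
#'   (factor with levels Querying, Accessing, Evaluating, Using, Discarding).
#' @examples
#' activity_codes()
#' @export
activity_codes <- function() {
  tibble::tibble(
    code = .activity_codes,
    stage = factor(.activity_stages, levels = .stage_levels)
  )
}

#' Look up the stage of an activity code
#'
#' @param code Character vector of activity codes.
#' @return Character vector of stage names; `NA` for unknown codes.
#' @examples
#' activity_stage(c("Q:NewQ", "U:UseHI"))
#' @export
activity_stage <- function(code) {
  unname(.activity_stages[code])
}

#' Assemble a session log tibble
#'
#' Builds the standard long-format session log used throughout the package:
#' one row per activity, ordered by step within session. A session is one
#' participant working on one health topic, so `session_id` is formed as
#' `participant_id.topic_id`.
#'
#' @param activities A named list; each element is a character vector of
#'   activity codes for one session, named by session id, or unnamed (ids
#'   `s1`, `s2`, ... are generated).
#' @param group Optional familiarity label(s) (`"L1"`, `"L2"`, `"L3"`),
#'   recycled across sessions.
#' @param participant_id,topic_id Optional vectors recycled across sessions;
#'   default to the session id and topic 1.
#' @return A session log tibble with columns `session_id`, `participant_id`,
#'   `topic_id`, `group`, `step`, `activity`.
#' @examples
#' sessions_tbl(list(c("Q:AccSE", "Q:NewQ", "E:ExamSR")), group = "L1")
#' @export
sessions_tbl <- function(activities, group = NA_character_,
                         participant_id = NULL, topic_id = 1L) {
  stopifnot(is.list(activities))
  n <- length(activities)
  if (n == 0) {
    return(tibble::tibble(
      session_id = character(), participant_id = character(),
      topic_id = integer(), group = character(),
      step = integer(), activity = character()
    ))
  }
  ids <- names(activities)
  if (is.null(ids) || any(ids == "")) ids <- paste0("s", seq_len(n))
  group <- rep_len(as.character(group), n)
  participant_id <- rep_len(if (is.null(participant_id)) ids else participant_id, n)
  topic_id <- rep_len(as.integer(topic_id), n)
  purrr::map_dfr(seq_len(n), function(i) {
    acts <- as.character(activities[[i]])
    tibble::tibble(
      session_id = ids[[i]],
      participant_id = participant_id[[i]],
      topic_id = topic_id[[i]],
      group = group[[i]],
      step = seq_along(acts),
      activity = acts
    )
  })
}

# Internal: split a session log into a named list of activity-code vectors,
# ordered by step. Assumes validated input.
.session_seqs <- function(sessions) {
  stopifnot(all(c("session_id", "step", "activity") %in% names(sessions)))
  sessions <- dplyr::arrange(sessions, .data$session_id, .data$step)
  split(sessions$activity, sessions$session_id)
}

# Internal: one familiarity label per session id (error on mixed labels).
.session_groups <- function(sessions) {
  g <- dplyr::distinct(sessions, .data$session_id, .data$group)
  dup <- g$session_id[duplicated(g$session_id)]
  if (length(dup) > 0) {
    stop("sessions with conflicting group labels: ", paste(dup, collapse = ", "))
  }
  stats::setNames(g$group, g$session_id)
}

#' Validate a session log
#'
#' Checks every session against the closed 18-code alphabet and the step
#' numbering convention (consecutive integers from 1). Violations are
#' returned, not raised, so corpora can be audited and cleaned; the analysis
#' functions exclude offending sessions.
#'
#' @param sessions A session log tibble (see [sessions_tbl()]).
#' @return A tibble of violations with columns `session_id`, `step`
#'   (`NA` for session-level problems) and `problem`. Zero rows means the
#'   log is fully valid.
#' @examples
#' log <- sessions_tbl(list(c("Q:AccSE", "X:Foo")))
#' validate_sessions(log)
#' @export
validate_sessions <- function(sessions) {
  if (is.character(sessions)) {
    # a single session given as a bare vector of activity codes
    if (length(sessions) == 0) {
      return(tibble::tibble(
        session_id = "s1", step = NA_integer_, problem = "empty session"
      ))
    }
    sessions <- sessions_tbl(list(sessions))
  }
  req <- c("session_id", "step", "activity")
  miss <- setdiff(req, names(sessions))
  if (length(miss) > 0) {
    stop("session log is missing columns: ", paste(miss, collapse = ", "))
  }
  out <- list()
  bad <- dplyr::filter(sessions, !(.data$activity %in% .activity_codes))
  if (nrow(bad) > 0) {
    out$codes <- tibble::tibble(
      session_id = bad$session_id,
      step = as.integer(bad$step),
      problem = paste0("unknown activity code '", bad$activity, "'")
    )
  }
  steps <- sessions |>
    dplyr::group_by(.data$session_id) |>
    dplyr::summarise(
      ok = length(.data$step) > 0 &&
        identical(sort(as.integer(.data$step)), seq_along(.data$step)),
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$ok)
  if (nrow(steps) > 0) {
    out$steps <- tibble::tibble(
      session_id = steps$session_id,
      step = NA_integer_,
      problem = "step indices are not consecutive from 1"
    )
  }
  if (nrow(sessions) == 0) {
    out$empty <- tibble::tibble(
      session_id = NA_character_, step = NA_integer_,
      problem = "empty session log"
    )
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      session_id = character(), step = integer(), problem = character()
    ))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$session_id, .data$step)
}

# Internal: drop sessions with any violation; warn with a count.
.qualify_sessions <- function(sessions, quiet = FALSE) {
  v <- validate_sessions(sessions)
  if (nrow(v) == 0) return(sessions)
  bad_ids <- unique(v$session_id[!is.na(v$session_id)])
  if (!quiet && length(bad_ids) > 0) {
    warning(length(bad_ids), " session(s) excluded after validation: ",
            paste(utils::head(bad_ids, 5), collapse = ", "),
            if (length(bad_ids) > 5) ", ..." else "")
  }
  dplyr::filter(sessions, !(.data$session_id %in% bad_ids))
}
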