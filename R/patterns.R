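# Frequent fixed-length activity patterns and behavioural categories.
#
# Pattern windows are contiguous, unpadded n-activity subsequences within a
# session (no boundary markers: mined patterns consist solely of activity
# codes, unlike the language models, which pad). A session of length L
# contributes max(0, L - n + 1) windows.

# Separator used when printing a pattern as a single string.
.PAT_SEP <- "\u2013" # en dash, the conventional way these patterns are printed

.pattern_string <- function(codes) paste(codes, collapse = .PAT_SEP)

#' Split a printed pattern string back into activity codes
#'
#' @param pattern Character vector of pattern strings (codes joined by an
#'   en dash).
#' @return A list of character vectors.
#' @export
pattern_codes <- function(pattern) {
  strsplit(pattern, .PAT_SEP, fixed = TRUE)
}

#' Count all length-n activity windows in a corpus
#'
#' @param sessions Session log tibble (typically one familiarity group).
#' @param n Window length (>= 2); the published analysis settles on n = 5.
#' @return A tibble `pattern`, `n` (window frequency), `share` (fraction of
#'   all windows), unranked, with attribute `total_windows`.
#' @examples
#' log <- sessions_tbl(list(c("Q:AccSE", "Q:NewQ", "E:ExamSR", "A:SelHI")))
#' extract_windows(log, n = 2)
#' @export
extract_windows <- function(sessions, n) {
  if (!is.numeric(n) || n < 2) stop("window length n must be >= 2")
  n <- as.integer(n)
  seqs <- .session_seqs(.qualify_sessions(sessions))
  wins <- unlist(lapply(seqs, function(s) {
    if (length(s) < n) return(character())
    m <- embed(s, n)[, n:1, drop = FALSE] # rows = windows in order
    apply(m, 1L, .pattern_string)
  }), use.names = FALSE)
  total <- length(wins)
  out <- if (total == 0) {
    tibble::tibble(pattern = character(), n = integer())
  } else {
    tw <- table(wins)
    tibble::tibble(pattern = names(tw), n = as.integer(tw))
  }
  out <- dplyr::mutate(out, share = if (total > 0) .data$n / total else numeric(0))
  attr(out, "total_windows") <- total
  attr(out, "window_length") <- n
  out
}

#' Top-k most frequent patterns
#'
#' Ranks patterns by descending frequency (ties broken lexicographically on
#' the pattern string) and reports the number of distinct pattern types
#' observed alongside the token-window total.
#'
#' @param windows Output of [extract_windows()].
#' @param k How many patterns to keep (default 20, the depth at which the
#'   published analysis stops because deeper patterns are too rare to
#'   characterise a group).
#' @return A tibble `rank`, `pattern`, `n`, `share_pct`, with attributes
#'   `distinct_patterns`, `total_windows`, `window_length`.
#' @export
top_patterns <- function(windows, k = 20) {
  stopifnot(k >= 1)
  out <- windows |>
    dplyr::arrange(dplyr::desc(.data$n), .data$pattern) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  share_pct = 100 * .data$share) |>
    dplyr::select("rank", "pattern", "n", "share_pct") |>
    utils::head(k)
  attr(out, "distinct_patterns") <- nrow(windows)
  attr(out, "total_windows") <- attr(windows, "total_windows")
  attr(out, "window_length") <- attr(windows, "window_length")
  out
}

# Category rule set, version 1. Categories follow the four behavioural
# groupings used to compare frequent patterns across familiarity levels:
#   1 query -> single health-item access -> evaluation
#   2 query -> multiple consecutive item selections
#   3 relevancy assessment of an evaluated item
#   4 continuing the search after using relevant information
.PATTERN_RULES_VERSION <- "1"

.categorize_one <- function(codes) {
  k <- length(codes)
  cats <- integer()
  is_q_entry <- codes %in% c("Q:AccSE", "Q:AccHW")
  is_q_query <- codes %in% c("Q:NewQ", "Q:ModQ")
  # positions where a querying prefix (entry point then query) starts
  prefix_at <- which(is_q_entry[-k] & is_q_query[-1])
  if (length(prefix_at) > 0) {
    for (i in prefix_at) {
      rest <- if (i + 2 <= k) codes[(i + 2):k] else character()
      sel <- which(rest == "A:SelHI")
      if (length(sel) == 1 && any(rest[-seq_len(sel)] == "E:EvalI")) {
        cats <- c(cats, 1L)
        break
      }
    }
    sel_codes <- c("A:SelHI", "A:SelGI")
    for (i in prefix_at) {
      rest <- if (i + 2 <= k) codes[(i + 2):k] else character()
      runs <- rle(rest %in% sel_codes)
      if (any(runs$values & runs$lengths >= 2)) {
        cats <- c(cats, 2L)
        break
      }
    }
  }
  assess <- c("U:UseHI", "U:UseGI", "D:DisHI", "D:DisGI")
  if (any(codes[-k] == "E:EvalI" & codes[-1] %in% assess)) cats <- c(cats, 3L)
  use_at <- which(codes %in% c("U:UseHI", "U:UseGI"))
  cont <- codes %in% c("Q:AccSE", "Q:AccHW", "Q:NewQ", "Q:ModQ", "E:ExamSR")
  if (length(use_at) > 0 && any(cont & seq_len(k) > min(use_at))) {
    cats <- c(cats, 4L)
  }
  sort(unique(cats))
}

#' Tag an activity pattern with behavioural categories
#'
#' Applies the versioned rule set for the four behavioural categories:
#' (1) a querying prefix (search engine or health website entry followed by a
#' new/modified query) followed in the window by exactly one health-item
#' selection (`A:SelHI`) and a subsequent evaluation (`E:EvalI`);
#' (2) a querying prefix followed by a run of two or more consecutive item
#' selections (`A:SelHI`/`A:SelGI`); (3) an evaluation immediately followed
#' by a use/discard assessment (`U:UseHI`, `U:UseGI`, `D:DisHI`, `D:DisGI`);
#' (4) a use activity followed later in the window by a querying-stage
#' activity or re-examination of results (`E:ExamSR`). A pattern can match
#' several categories; no match yields an empty set.
#'
#' @param pattern A character vector of activity codes, or a single pattern
#'   string as produced by [extract_windows()].
#' @return Integer vector of matched categories (possibly empty), with
#'   attribute `rules_version`.
#' @examples
#' categorize_pattern(c("Q:AccSE", "Q:ModQ", "E:ExamSR", "A:SelHI", "E:EvalI"))
#' @export
categorize_pattern <- function(pattern) {
  if (length(pattern) == 1 && grepl(.PAT_SEP, pattern, fixed = TRUE)) {
    pattern <- pattern_codes(pattern)[[1]]
  }
  if (length(pattern) < 2) stop("pattern must have length >= 2")
  structure(.categorize_one(pattern), rules_version = .PATTERN_RULES_VERSION)
}

#' Per-group frequent patterns and category comparison
#'
#' For each familiarity group: the top-k pattern table; across groups: the
#' summed top-k frequency share matched by each behavioural category.
#'
#' @param sessions Labeled session log tibble.
#' @param n Window length (default 5).
#' @param k Top-k depth (default 20).
#' @return A `pattern_summary` object: list with `tables` (named list of
#'   top-k tibbles, each with a `categories` list-column), `categories`
#'   (tibble `group`, `category`, `n`, `share_pct` of the group's windows
#'   covered by top-k patterns matching the category) and `params`.
#' @examples
#' log <- simulate_corpus(n_sessions = 40, seed = 2)
#' ps <- pattern_summary(log, n = 5, k = 10)
#' ps$categories
#' @export
pattern_summary <- function(sessions, n = 5, k = 20) {
  if (!"group" %in% names(sessions) || anyNA(sessions$group)) {
    stop("all sessions must carry a familiarity group label")
  }
  groups <- sort(unique(sessions$group))
  tables <- purrr::map(
    stats::setNames(groups, groups),
    function(g) {
      sub <- dplyr::filter(sessions, .data$group == g)
      wins <- extract_windows(sub, n = n)
      if (nrow(wins) == 0) {
        warning("group ", g, " has no windows of length ", n)
      }
      tp <- top_patterns(wins, k = k)
      tp$categories <- purrr::map(tp$pattern, function(p) as.integer(categorize_pattern(p)))
      tp
    }
  )
  cat_tbl <- purrr::map_dfr(groups, function(g) {
    tp <- tables[[g]]
    purrr::map_dfr(1:4, function(cc) {
      hit <- purrr::map_lgl(tp$categories, function(x) cc %in% x)
      tibble::tibble(
        group = g, category = cc,
        n = sum(tp$n[hit]),
        share_pct = sum(tp$share_pct[hit])
      )
    })
  })
  structure(
    list(tables = tables, categories = cat_tbl,
         params = list(n = n, k = k, rules_version = .PATTERN_RULES_VERSION)),
    class = "pattern_summary"
  )
}

#' @export
print.pattern_summary <- function(x, ...) {
  cat("Frequent ", x$params$n, "-activity patterns (top ", x$params$k,
      " per group; category rules v", x$params$rules_version, ")\n", sep = "")
  for (g in names(x$tables)) {
    cat("\nGroup ", g, " (", attr(x$tables[[g]], "distinct_patterns"),
        " distinct patterns / ", attr(x$tables[[g]], "total_windows"),
        " windows):\n", sep = "")
    print(utils::head(x$tables[[g]], 5))
  }
  invisible(x)
}
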