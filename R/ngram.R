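# N-gram language models of activity sequences with interpolated
# Witten-Bell smoothing, held-out perplexity and order selection.
#
# Boundary convention: an order-n model prepends n-1 start markers "<s>" to
# each session and appends one end marker "</s>". Start markers are never
# predicted; the end marker is predicted and counted in the token total. The
# predictable vocabulary is therefore the 18 activity codes plus "</s>"
# (19 symbols), and the vocabulary is closed: out-of-vocabulary codes are an
# error, not an unknown-word state.
#
# Interpolated Witten-Bell: with c(h, w) the continuation count, c(h) the
# history total and T(h) the number of distinct symbols seen after h,
#   p(w | h) = (c(h, w) + T(h) * p(w | h')) / (c(h) + T(h)),
# where h' drops the oldest symbol of h. A history never observed falls
# through to the lower order; the order-0 base distribution is uniform over
# the predictable vocabulary.

.predict_vocab <- function() c(.activity_codes, .EOS)

# Sentinel key for the empty (order-0) history: environments cannot hold a
# variable with an empty name.
.H0 <- "<root>"

# Build an environment keyed by history string -> named numeric count vector.
.level_env <- function(h, w) {
  env <- new.env(parent = emptyenv(), size = max(16L, length(unique(h))))
  if (length(h) > 0) {
    sp <- split(w, h)
    for (key in names(sp)) {
      tw <- table(sp[[key]])
      env[[key]] <- stats::setNames(as.numeric(tw), names(tw))
    }
  }
  env
}

#' Split a session corpus into training and test sessions
#'
#' Seeded, session-level random split: a session is the natural sentence unit
#' for the language models, so it goes wholly to one side. The training share
#' is `round(fraction * n)` sessions, clamped so both sides are nonempty.
#'
#' @param sessions Session log tibble with at least 2 sessions.
#' @param fraction Training fraction in (0, 1); default 0.8.
#' @param seed Integer seed; the same corpus, fraction and seed always give
#'   the identical split.
#' @return A list with tibbles `train` and `test` and the `fraction` and
#'   `seed` used.
#' @export
split_corpus <- function(sessions, fraction = 0.8, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  ids <- sort(unique(sessions$session_id))
  if (length(ids) < 2) stop("need at least 2 sessions to split")
  n_train <- round(fraction * length(ids))
  n_train <- min(max(n_train, 1L), length(ids) - 1L)
  train_ids <- withr::with_seed(seed, sample(ids, n_train))
  list(
    train = dplyr::filter(sessions, .data$session_id %in% train_ids),
    test = dplyr::filter(sessions, !(.data$session_id %in% train_ids)),
    fraction = fraction,
    seed = seed
  )
}

# Internal constructor; exposed to tests via :::.
.new_ngram_model <- function(order, levels, n_sessions = 0L, n_tokens = 0L) {
  structure(
    list(
      order = as.integer(order),
      vocab = .predict_vocab(),
      levels = levels,
      n_sessions = n_sessions,
      n_tokens = n_tokens,
      smoothing = "interpolated Witten-Bell"
    ),
    class = "ngram_model"
  )
}

#' Fit an n-gram model of activity sequences
#'
#' Counts n-grams (and all lower orders) over boundary-padded sessions and
#' stores them for interpolated Witten-Bell conditional probabilities; see
#' the package vignette for the smoothing and boundary conventions.
#'
#' @param sessions Nonempty session log tibble (the training corpus).
#' @param order Model order n >= 1 (n - 1 symbols of history). The published
#'   sweep for this analysis is orders 2-7.
#' @return An `ngram_model` object.
#' @examples
#' log <- simulate_corpus(n_sessions = 40, seed = 1)
#' m <- fit_ngram(log, order = 3)
#' glance(m)
#' @export
fit_ngram <- function(sessions, order) {
  if (!is.numeric(order) || order < 1) stop("order must be >= 1")
  order <- as.integer(order)
  sessions <- .qualify_sessions(sessions)
  seqs <- .session_seqs(sessions)
  if (length(seqs) == 0) stop("training corpus is empty")
  oov <- setdiff(unique(unlist(seqs, use.names = FALSE)), .activity_codes)
  if (length(oov) > 0) stop("out-of-vocabulary codes: ", paste(oov, collapse = ", "))
  # (history, next) pairs per level, pooled over sessions
  levels <- vector("list", order)
  hs <- vector("list", order)
  ws <- vector("list", order)
  for (i in seq_len(order)) {
    hs[[i]] <- vector("list", length(seqs))
    ws[[i]] <- vector("list", length(seqs))
  }
  for (s in seq_along(seqs)) {
    toks <- c(rep(.BOS, order - 1L), seqs[[s]], .EOS)
    pos <- order:length(toks) # predicted positions
    for (m in 0:(order - 1L)) {
      ws[[m + 1L]][[s]] <- toks[pos]
      if (m == 0) {
        hs[[1L]][[s]] <- rep(.H0, length(pos))
      } else {
        hmat <- vapply(1:m, function(d) toks[pos - (m - d + 1L)], character(length(pos)))
        if (length(pos) == 1L) hmat <- matrix(hmat, nrow = 1L)
        hs[[m + 1L]][[s]] <- apply(hmat, 1L, paste, collapse = " ")
      }
    }
  }
  for (m in 0:(order - 1L)) {
    levels[[m + 1L]] <- .level_env(
      unlist(hs[[m + 1L]], use.names = FALSE),
      unlist(ws[[m + 1L]], use.names = FALSE)
    )
  }
  n_tokens <- sum(lengths(seqs)) + length(seqs)
  .new_ngram_model(order, levels, n_sessions = length(seqs), n_tokens = n_tokens)
}

#' Conditional probability under an n-gram model
#'
#' @param model An `ngram_model`.
#' @param history Character vector of preceding symbols (may be empty or
#'   include the start marker); only the last `order - 1` are used.
#' @param word Single symbol to predict (an activity code or the end marker).
#' @return The interpolated Witten-Bell probability `p(word | history)`.
#' @export
ngram_prob <- function(model, history, word) {
  stopifnot(inherits(model, "ngram_model"))
  m <- min(length(history), model$order - 1L)
  history <- if (m > 0) history[(length(history) - m + 1L):length(history)] else character()
  .wb_prob(model, history, word)
}

.wb_prob <- function(model, h, w) {
  V <- length(model$vocab)
  m <- length(h)
  if (m == 0) {
    cv <- model$levels[[1L]][[.H0]]
    if (is.null(cv)) return(1 / V)
    chw <- cv[w]
    if (is.na(chw)) chw <- 0
    Th <- length(cv)
    return(unname((chw + Th / V) / (sum(cv) + Th)))
  }
  p_low <- .wb_prob(model, h[-1L], w)
  cv <- model$levels[[m + 1L]][[paste(h, collapse = " ")]]
  if (is.null(cv)) return(p_low)
  chw <- cv[w]
  if (is.na(chw)) chw <- 0
  Th <- length(cv)
  unname((chw + Th * p_low) / (sum(cv) + Th))
}

#' Log-probability of one session under an n-gram model
#'
#' Sums `log p(w_k | previous n-1 symbols)` over the session's activities
#' plus the end marker, with start-marker padding. The token count includes
#' the end marker and excludes start markers.
#'
#' @param model An `ngram_model`.
#' @param activities Character vector of activity codes (one session), or a
#'   one-session log tibble.
#' @return A list with `logprob` (natural log) and `tokens`.
#' @export
sequence_logprob <- function(model, activities) {
  stopifnot(inherits(model, "ngram_model"))
  if (is.data.frame(activities)) {
    seqs <- .session_seqs(activities)
    if (length(seqs) != 1) stop("expected a single session")
    activities <- seqs[[1]]
  }
  oov <- setdiff(activities, .activity_codes)
  if (length(oov) > 0) stop("out-of-vocabulary codes: ", paste(oov, collapse = ", "))
  n <- model$order
  toks <- c(rep(.BOS, n - 1L), activities, .EOS)
  lp <- 0
  for (t in n:length(toks)) {
    h <- if (n > 1) toks[(t - n + 1L):(t - 1L)] else character()
    lp <- lp + log(.wb_prob(model, h, toks[t]))
  }
  list(logprob = lp, tokens = length(activities) + 1L)
}

#' Perplexity of an n-gram model on held-out sessions
#'
#' Perplexity is the exponentiated average negative log-probability per
#' token, pooled over all test sessions: the geometric-average branching
#' factor of the activity "language" under the model. Lower is better; a
#' model that ignores all structure scores exactly the predictable
#' vocabulary size (19).
#'
#' @param model An `ngram_model`.
#' @param sessions Nonempty session log tibble (the test corpus).
#' @return One-row tibble: `order`, `perplexity`, `tokens`, `logprob`.
#' @export
perplexity <- function(model, sessions) {
  stopifnot(inherits(model, "ngram_model"))
  seqs <- .session_seqs(.qualify_sessions(sessions))
  if (length(seqs) == 0) stop("test corpus is empty")
  res <- purrr::map(seqs, function(s) sequence_logprob(model, s))
  lp <- sum(purrr::map_dbl(res, "logprob"))
  tok <- sum(purrr::map_int(res, "tokens"))
  tibble::tibble(
    order = model$order,
    perplexity = exp(-lp / tok),
    tokens = tok,
    logprob = lp
  )
}

#' Select the n-gram order by held-out perplexity
#'
#' Makes one seeded train/test split, fits a model per candidate order on the
#' shared training sessions, evaluates perplexity on the shared test
#' sessions, and picks the order with the lowest perplexity (ties go to the
#' smaller order).
#'
#' @param sessions Session log tibble.
#' @param orders Candidate orders; default 2:7.
#' @param fraction Training fraction for [split_corpus()].
#' @param seed Seed for the split.
#' @return An `order_selection` object: list with `results` (one row per
#'   order), `best_order`, `fraction`, `seed`.
#' @examples
#' log <- simulate_corpus(n_sessions = 60, seed = 1)
#' sel <- select_order(log, orders = 2:4, seed = 7)
#' sel$best_order
#' @export
select_order <- function(sessions, orders = 2:7, fraction = 0.8, seed = 1L) {
  split <- split_corpus(sessions, fraction = fraction, seed = seed)
  results <- purrr::map_dfr(orders, function(n) {
    perplexity(fit_ngram(split$train, order = n), split$test)
  })
  best <- results$order[order(results$perplexity, results$order)][1]
  structure(
    list(results = results, best_order = best,
         fraction = fraction, seed = seed),
    class = "order_selection"
  )
}

#' @export
print.order_selection <- function(x, ...) {
  cat("Perplexity by n-gram order (80/20-style held-out split, seed ",
      x$seed, "):\n", sep = "")
  print(x$results)
  cat("Best order:", x$best_order, "\n")
  invisible(x)
}

#' @export
tidy.order_selection <- function(x, ...) x$results

#' @export
glance.order_selection <- function(x, ...) {
  tibble::tibble(
    best_order = x$best_order,
    min_perplexity = min(x$results$perplexity),
    orders_tried = nrow(x$results),
    fraction = x$fraction,
    seed = x$seed
  )
}

#' @export
glance.ngram_model <- function(x, ...) {
  tibble::tibble(
    order = x$order,
    vocab_size = length(x$vocab),
    n_sessions = x$n_sessions,
    n_tokens = x$n_tokens,
    contexts = sum(vapply(x$levels, function(e) length(ls(e, all.names = TRUE)), integer(1))),
    smoothing = x$smoothing
  )
}

#' @export
print.ngram_model <- function(x, ...) {
  cat("Activity n-gram model: order", x$order, "|", x$smoothing, "\n")
  cat("Trained on", x$n_sessions, "sessions /", x$n_tokens, "tokens;",
      "closed vocabulary of", length(x$vocab), "predictable symbols\n")
  invisible(x)
}

#' Write an n-gram model as an ARPA-style plain-text file
#'
#' Writes the observed n-grams of every level with their interpolated
#' conditional probabilities as base-10 logs, in the usual `\\data\\` /
#' `\\n-grams:` layout. Because the model interpolates at query time, the
#' file carries final probabilities for observed n-grams and no back-off
#' weight column; unlisted n-grams fall back to the lower order at the
#' reader's discretion.
#'
#' @param model An `ngram_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_arpa <- function(model, path) {
  stopifnot(inherits(model, "ngram_model"))
  lines <- c("\\data\\")
  grams <- vector("list", model$order)
  for (m in 0:(model$order - 1L)) {
    env <- model$levels[[m + 1L]]
    keys <- sort(ls(env, all.names = TRUE))
    rows <- character()
    for (key in keys) {
      cv <- env[[key]]
      hvec <- if (key == .H0) character() else strsplit(key, " ", fixed = TRUE)[[1]]
      for (w in sort(names(cv))) {
        lp <- log10(.wb_prob(model, hvec, w))
        rows <- c(rows, sprintf("%.6f\t%s", lp, paste(c(hvec, w), collapse = " ")))
      }
    }
    grams[[m + 1L]] <- rows
    lines <- c(lines, sprintf("ngram %d=%d", m + 1L, length(rows)))
  }
  for (m in 0:(model$order - 1L)) {
    lines <- c(lines, "", sprintf("\\%d-grams:", m + 1L), grams[[m + 1L]])
  }
  lines <- c(lines, "", "\\end\\")
  writeLines(lines, path)
  invisible(path)
}
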