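# Synthetic session and questionnaire generator.
#
# The generator emulates the statistical structure the analysis assumes:
# per-group first-order Markov kernels anchored on the published top-10
# transition shares, session starts at a search engine (or, for familiar
# searchers, directly at a consumer health website), session termination
# after information-use activities so every session contains at least one
# use activity and ends in the using stage, and session lengths targeting
# mean 28.7 (SD 23.27) activities within [6, 221].

# Published top-10 first-order transitions per familiarity group (counts and
# group transition totals). These printed cells are the calibration anchors
# for the default kernels; all unprinted mass is smoothed (see .build_kernel).
.anchor_totals <- c(L1 = 2363L, L2 = 1153L, L3 = 919L)

.top10_anchors <- tibble::tribble(
  ~group, ~from, ~to, ~n,
  "L1", "E:ExamSR", "A:SelHI", 188L,
  "L1", "A:SelHI", "E:EvalI", 181L,
  "L1", "E:EvalI", "D:DisHI", 160L,
  "L1", "Q:ModQ", "E:ExamSR", 158L,
  "L1", "Q:AccSE", "Q:ModQ", 121L,
  "L1", "E:EvalI", "U:UseHI", 120L,
  "L1", "A:XplorF", "E:EvalI", 91L,
  "L1", "E:EvalI", "A:XplorF", 88L,
  "L1", "Q:AccSE", "Q:NewQ", 75L,
  "L1", "Q:NewQ", "E:ExamSR", 75L,
  "L2", "E:ExamSR", "A:SelHI", 113L,
  "L2", "A:SelHI", "E:EvalI", 101L,
  "L2", "E:EvalI", "U:UseHI", 94L,
  "L2", "Q:ModQ", "E:ExamSR", 75L,
  "L2", "Q:NewQ", "E:ExamSR", 64L,
  "L2", "Q:AccSE", "Q:NewQ", 63L,
  "L2", "Q:AccSE", "Q:ModQ", 52L,
  "L2", "A:SelHI", "A:SelHI", 40L,
  "L2", "A:SelGI", "E:EvalI", 39L,
  "L2", "E:EvalI", "D:DisHI", 36L,
  "L3", "E:ExamSR", "A:SelHI", 102L,
  "L3", "A:SelHI", "E:EvalI", 101L,
  "L3", "E:EvalI", "U:UseHI", 81L,
  "L3", "Q:NewQ", "E:ExamSR", 56L,
  "L3", "E:EvalI", "D:DisHI", 51L,
  "L3", "Q:AccSE", "Q:NewQ", 48L,
  "L3", "A:SelHI", "A:SelHI", 44L,
  "L3", "Q:ModQ", "E:ExamSR", 44L,
  "L3", "Q:AccSE", "Q:ModQ", 35L,
  "L3", "A:XplorF", "E:EvalI", 24L
)

#' Published top-10 transition anchors
#'
#' The per-group top-10 first-order transition counts (with group transition
#' totals as attribute `totals`) that calibrate the default generator
#' kernels. Also convenient for arithmetic checks on ranked transition
#' reports.
#'
#' @return Tibble `group`, `from`, `to`, `n`; attribute `totals`.
#' @export
transition_anchors <- function() {
  out <- .top10_anchors
  attr(out, "totals") <- .anchor_totals
  out
}

# Destination-state weights used to smooth unprinted kernel mass. The shape
# loosely follows the reported activity mix (evaluating > accessing >
# querying > using/discarding); the floor of 4 is a calibration choice that
# keeps every state's stationary share large enough for kernel-recovery
# checks on simulated corpora (see the vignette).
.dest_weights <- function(label) {
  w <- c(
    "Q:AccSE" = 5, "Q:AccHW" = 4, "Q:NewQ" = 5, "Q:ModQ" = 6,
    "A:SelHI" = 9, "A:SelGI" = 5, "A:XplorF" = 5, "A:AccB" = 5,
    "E:ExamSR" = 10, "E:DisSR" = 4, "E:EvalI" = 12, "E:FindQ" = 4,
    "U:UseHI" = 6, "U:UseGI" = 4,
    "D:DisHI" = 6, "D:DisGI" = 4, "D:UnchkHI" = 4, "D:UnchkGI" = 4
  )
  if (label == "L3") {
    w["Q:ModQ"] <- 4 # familiar searchers reformulate less
    w["Q:AccHW"] <- 5
  }
  w[.activity_codes]
}

# Anchored + smoothed row-stochastic kernel for one group.
.build_kernel <- function(label) {
  anchors <- .top10_anchors[.top10_anchors$group == label, ]
  K <- length(.activity_codes)
  W <- matrix(0, K, K, dimnames = list(.activity_codes, .activity_codes))
  W[cbind(anchors$from, anchors$to)] <- anchors$n
  leftover <- .anchor_totals[[label]] - sum(anchors$n)
  dw <- .dest_weights(label)
  filler <- outer(dw / sum(dw), dw)
  filler[W > 0] <- 0
  filler <- filler * (leftover / sum(filler))
  W <- W + filler
  W / rowSums(W)
}

#' Construct a session generator profile
#'
#' A profile bundles everything needed to simulate sessions for one group:
#' a Markov kernel (order 1 over the 18 codes, or a higher-order kernel
#' keyed by history tuples), a start rule, a stop rule and length targets.
#'
#' @param label Group label attached to simulated sessions.
#' @param kernel Row-stochastic matrix. For `key_order = 1`, rows and columns
#'   are the 18 activity codes; for higher orders, rows are space-separated
#'   history keys of `key_order` codes and columns the 18 codes.
#' @param start Named probability vector over activity codes for the first
#'   activity (order-1 profiles).
#' @param start_seq Fixed opening activity sequence (required when
#'   `key_order > 1`; must be at least `key_order` long).
#' @param key_order History length of the kernel (default 1).
#' @param stop_states After emitting one of these states the session ends
#'   with probability `stop_prob` (only once `min_len` is reached).
#' @param stop_prob Per-opportunity stop probability.
#' @param min_len,max_len Hard length bounds; the session is forced to end at
#'   `max_len` regardless of its current state.
#' @param length_mean,length_sd Length targets recorded as metadata.
#' @return A `generator_profile` object.
#' @export
generator_profile <- function(label, kernel, start = NULL, start_seq = NULL,
                              key_order = 1L, stop_states, stop_prob,
                              min_len = 6L, max_len = 221L,
                              length_mean = NA_real_, length_sd = NA_real_) {
  kernel <- as.matrix(kernel)
  if (any(kernel < 0) || any(abs(rowSums(kernel) - 1) > 1e-9)) {
    stop("kernel rows must be nonnegative and sum to 1")
  }
  if (!identical(colnames(kernel), .activity_codes)) {
    stop("kernel columns must be the 18 activity codes in canonical order")
  }
  key_order <- as.integer(key_order)
  if (key_order == 1L) {
    if (is.null(start)) stop("order-1 profiles need a start distribution")
    if (abs(sum(start) - 1) > 1e-9) stop("start distribution must sum to 1")
  } else {
    if (is.null(start_seq) || length(start_seq) < key_order) {
      stop("higher-order profiles need start_seq of length >= key_order")
    }
  }
  if (min_len > max_len) stop("min_len must be <= max_len")
  structure(
    list(
      label = label, kernel = kernel, start = start, start_seq = start_seq,
      key_order = key_order, stop_states = stop_states, stop_prob = stop_prob,
      min_len = as.integer(min_len), max_len = as.integer(max_len),
      length_mean = length_mean, length_sd = length_sd
    ),
    class = "generator_profile"
  )
}

# Stop probabilities after a use-stage activity, calibrated numerically per
# group so simulated lengths hit the mean-28.7 target under each kernel
# (the use-stage visit rate differs between groups). See the vignette.
.default_stop_prob <- c(L1 = 0.4061, L2 = 0.2843, L3 = 0.2943)

#' Default per-group generator profiles
#'
#' Three profiles (L1, L2, L3) whose kernels are anchored on the published
#' top-10 transition counts per group, with unprinted mass smoothed over all
#' cells (see the vignette for the smoothing and its calibration role).
#' Unfamiliar searchers always start at a general search engine; the familiar
#' group places substantial start probability on going directly to a known
#' consumer health website. Sessions stop after use-stage activities
#' (`U:UseHI`, `U:UseGI`) with a group-calibrated probability, targeting
#' mean length 28.7 (SD 23.27) within [6, 221], so every simulated session
#' contains at least one information-use activity and ends in the using
#' stage.
#'
#' @return Named list of `generator_profile` objects for L1, L2, L3.
#' @examples
#' p <- default_profiles()
#' rowSums(p$L1$kernel)[1:3] # rows are probability distributions
#' @export
default_profiles <- function() {
  starts <- list(
    L1 = c("Q:AccSE" = 1.0),
    L2 = c("Q:AccSE" = 0.95, "Q:AccHW" = 0.05),
    L3 = c("Q:AccSE" = 0.70, "Q:AccHW" = 0.30)
  )
  purrr::imap(starts, function(st, lab) {
    start <- stats::setNames(rep(0, length(.activity_codes)), .activity_codes)
    start[names(st)] <- st
    generator_profile(
      label = lab,
      kernel = .build_kernel(lab),
      start = start,
      stop_states = .use_codes,
      stop_prob = .default_stop_prob[[lab]],
      min_len = 6L, max_len = 221L,
      length_mean = 28.7, length_sd = 23.27
    )
  })
}

#' Higher-order generator profile from a cyclic motif
#'
#' Builds a history-keyed kernel that repeats an activity motif: after any
#' history of `key_order` activities the motif's next activity follows with
#' probability `1 - noise`, and with probability `noise` a dedicated restart
#' activity (`reset_code`) is emitted, after which the motif starts over
#' from its first element. Because the restart pins the phase, the process
#' is an exact Markov chain of history length `key_order`; with a motif
#' whose length-`key_order` windows are unique but whose shorter windows are
#' ambiguous, shorter-history models are genuinely worse, making the profile
#' a ground truth for order-selection checks (a `key_order = 4` motif is
#' best captured by a 5-gram model).
#'
#' @param motif Character vector of activity codes, treated cyclically; its
#'   length-`key_order` windows must be distinct.
#' @param noise Per-step restart probability (default 0.1).
#' @param reset_code Activity code emitted on a restart; defaults to a code
#'   not used by the motif.
#' @param key_order History length (default `length(motif) - 1`).
#' @param stop_prob,min_len,max_len Stop rule (any state may stop).
#' @return A `generator_profile`.
#' @export
motif_profile <- function(motif, noise = 0.1, reset_code = NULL,
                          key_order = length(motif) - 1L,
                          stop_prob = 0.025, min_len = 20L, max_len = 200L) {
  stopifnot(all(motif %in% .activity_codes), key_order >= 1)
  alphabet <- unique(motif)
  if (length(alphabet) < 2) stop("motif must use at least 2 distinct codes")
  if (is.null(reset_code)) reset_code <- setdiff(.activity_codes, alphabet)[[1]]
  if (reset_code %in% alphabet) stop("reset_code must not appear in the motif")
  L <- length(motif)
  ext <- c(motif, motif[seq_len(key_order)]) # cyclic windows
  windows <- vapply(seq_len(L), function(i) {
    paste(ext[i:(i + key_order - 1L)], collapse = " ")
  }, character(1))
  if (anyDuplicated(windows)) {
    stop("motif windows of length key_order are not distinct")
  }
  full <- c(alphabet, reset_code)
  histories <- as.matrix(do.call(
    expand.grid,
    c(rep(list(full), key_order), stringsAsFactors = FALSE)
  ))
  keys <- apply(histories, 1L, paste, collapse = " ")
  # deterministic successor of a history: a restart pins the phase; an
  # uninterrupted history is located on the cycle
  succ <- vapply(seq_len(nrow(histories)), function(r) {
    h <- histories[r, ]
    j <- which(h == reset_code)
    if (length(j) > 0) {
      after <- length(h) - max(j) # motif elements emitted since the restart
      motif[[after + 1L]]
    } else {
      key <- paste(h, collapse = " ")
      i <- match(key, windows)
      if (is.na(i)) motif[[1L]] else ext[[i + key_order]] # off-cycle unreachable
    }
  }, character(1))
  kernel <- matrix(0, nrow = length(keys), ncol = length(.activity_codes),
                   dimnames = list(keys, .activity_codes))
  kernel[cbind(seq_along(keys), match(succ, .activity_codes))] <- 1 - noise
  kernel[, reset_code] <- kernel[, reset_code] + noise
  generator_profile(
    label = "motif", kernel = kernel,
    start_seq = motif, key_order = key_order,
    stop_states = .activity_codes, stop_prob = stop_prob,
    min_len = min_len, max_len = max_len
  )
}

#' Simulate sessions from a generator profile
#'
#' Vectorised across sessions: all active sessions advance one Markov step
#' per iteration, so simulating tens of thousands of sessions is cheap.
#'
#' @param profile A `generator_profile`.
#' @param n_sessions Number of sessions to simulate.
#' @param seed Optional integer seed (restores the RNG state afterwards);
#'   if `NULL`, the current RNG stream is used.
#' @param id_prefix Prefix for session/participant ids.
#' @return A labeled session log tibble.
#' @export
simulate_sessions <- function(profile, n_sessions, seed = NULL,
                              id_prefix = profile$label) {
  stopifnot(inherits(profile, "generator_profile"), n_sessions >= 0)
  if (n_sessions == 0) {
    return(sessions_tbl(list()))
  }
  run <- function() .simulate_engine(profile, n_sessions)
  seqs <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  ids <- sprintf("%s_%05d", id_prefix, seq_len(n_sessions))
  lens <- lengths(seqs)
  tibble::tibble(
    session_id = rep(ids, lens),
    participant_id = rep(ids, lens),
    topic_id = rep(1L + (seq_len(n_sessions) - 1L) %% 4L, lens),
    group = if (profile$label %in% c("L1", "L2", "L3")) profile$label else NA_character_,
    step = sequence(lens),
    activity = unlist(seqs, use.names = FALSE)
  )
}

.simulate_engine <- function(profile, n) {
  K <- length(.activity_codes)
  kernel <- profile$kernel
  cum <- t(apply(kernel, 1L, cumsum))
  m <- profile$key_order
  max_len <- profile$max_len
  states <- matrix(0L, nrow = n, ncol = max_len)
  stop_idx <- which(.activity_codes %in% profile$stop_states)
  if (m == 1L) {
    first <- sample.int(K, n, replace = TRUE, prob = profile$start)
    states[, 1L] <- first
    t0 <- 1L
  } else {
    sidx <- match(profile$start_seq, .activity_codes)
    t0 <- length(sidx)
    states[, seq_len(t0)] <- matrix(rep(sidx, each = n), nrow = n)
  }
  len <- rep(0L, n)
  alive <- rep(TRUE, n)
  # honour stop opportunities within the seeded prefix only at/after min_len,
  # which the prefix never reaches for the default profiles
  t <- t0
  while (any(alive) && t < max_len) {
    idx <- which(alive)
    if (m == 1L) {
      rows <- states[idx, t]
    } else {
      hist_keys <- apply(
        matrix(.activity_codes[states[idx, (t - m + 1L):t, drop = FALSE]],
               nrow = length(idx)),
        1L, paste, collapse = " "
      )
      rows <- match(hist_keys, rownames(kernel))
      if (anyNA(rows)) stop("history not covered by the kernel")
    }
    u <- stats::runif(length(idx))
    nxt <- 1L + as.integer(rowSums(u > cum[rows, , drop = FALSE]))
    t <- t + 1L
    states[idx, t] <- nxt
    can_stop <- nxt %in% stop_idx & t >= profile$min_len
    stopping <- can_stop & stats::runif(length(idx)) < profile$stop_prob
    done <- idx[stopping]
    len[done] <- t
    alive[done] <- FALSE
  }
  len[alive] <- max_len
  lapply(seq_len(n), function(i) .activity_codes[states[i, seq_len(len[i])]])
}

#' Simulate a labeled multi-group session corpus
#'
#' @param n_sessions Sessions per group: a scalar, or a named vector keyed by
#'   profile label.
#' @param profiles Named list of `generator_profile`s (default
#'   [default_profiles()]).
#' @param seed Integer seed; a fixed seed gives a byte-identical corpus.
#' @return A labeled session log tibble with a `manifest` attribute recording
#'   seed, sizes, RNG kind and a numeric fingerprint of each kernel.
#' @examples
#' log <- simulate_corpus(n_sessions = 10, seed = 1)
#' dplyr::count(log, group)
#' @export
simulate_corpus <- function(n_sessions = 100, profiles = default_profiles(),
                            seed = 1L) {
  labs <- names(profiles)
  if (is.null(labs)) stop("profiles must be a named list")
  sizes <- if (length(n_sessions) == 1) {
    stats::setNames(rep(as.integer(n_sessions), length(labs)), labs)
  } else {
    if (!all(labs %in% names(n_sessions))) {
      stop("n_sessions must name every profile label")
    }
    n_sessions[labs]
  }
  out <- withr::with_seed(seed, {
    purrr::map_dfr(labs, function(lab) {
      simulate_sessions(profiles[[lab]], sizes[[lab]], seed = NULL,
                        id_prefix = lab)
    })
  })
  attr(out, "manifest") <- list(
    seed = seed,
    n_sessions = as.list(sizes),
    rng_kind = "Mersenne-Twister",
    kernel_fingerprint = purrr::map_dbl(
      profiles, function(p) sum(p$kernel * seq_along(p$kernel))
    )
  )
  out
}

# Per-label Bernoulli probabilities that an item is answered correctly, by
# section. Chosen so scoring a simulated questionnaire recovers the
# requested label with probability >= 0.95: L1 recognises some surface
# terminology only, L2 also understands consumer-friendly terminology, L3
# additionally masters advanced terminology.
.default_q_rates <- list(
  L1 = c(0.50, 0.01, 0.00),
  L2 = c(0.95, 0.90, 0.00),
  L3 = c(0.99, 0.95, 0.90)
)

#' Simulate questionnaire responses for labeled participants
#'
#' Generates the full 24-item response set (three sections x four topics x
#' two items) per participant, with per-section correctness probabilities
#' chosen so that [score_familiarity()] recovers the requested label with
#' high probability. Items not answered correctly are marked `"incorrect"`
#' or `"unknown"` at random.
#'
#' @param labels Either a named character vector `participant_id -> label`
#'   (the label applies to all four topics) or a tibble with columns
#'   `participant_id`, `topic_id`, `label`.
#' @param rates Named list of per-section correctness probabilities per
#'   label; see `seekr:::.default_q_rates` for the defaults.
#' @param seed Optional integer seed.
#' @return A questionnaire response tibble (columns `participant_id`,
#'   `section`, `topic_id`, `item_index`, `status`).
#' @examples
#' resp <- simulate_questionnaire(c(p1 = "L1", p2 = "L3"), seed = 1)
#' score_familiarity(resp)
#' @export
simulate_questionnaire <- function(labels, rates = .default_q_rates,
                                   seed = NULL) {
  if (is.character(labels)) {
    if (is.null(names(labels))) stop("labels vector must be named by participant")
    labels <- tidyr::expand_grid(
      participant_id = names(labels), topic_id = 1:4
    ) |>
      dplyr::mutate(label = unname(labels[.data$participant_id]))
  }
  stopifnot(all(c("participant_id", "topic_id", "label") %in% names(labels)))
  if (!all(labels$label %in% names(rates))) {
    stop("no rates for label(s): ",
         paste(setdiff(unique(labels$label), names(rates)), collapse = ", "))
  }
  gen <- function() {
    labels |>
      tidyr::expand_grid(section = 1:3, item_index = 1:2) |>
      dplyr::mutate(
        p = purrr::map2_dbl(.data$label, .data$section, function(l, s) rates[[l]][[s]]),
        correct = stats::runif(dplyr::n()) < .data$p,
        status = dplyr::if_else(
          .data$correct, "correct",
          dplyr::if_else(stats::runif(dplyr::n()) < 0.5, "incorrect", "unknown")
        )
      ) |>
      dplyr::select("participant_id", "section", "topic_id", "item_index", "status")
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
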