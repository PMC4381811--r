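# Shared fixtures and independent oracles used across the suite.

# A small sub-alphabet for toy Markov chains.
c3 <- c("Q:AccSE", "E:ExamSR", "A:SelHI")

# Simulate fixed-length first-order chains over an arbitrary named kernel,
# vectorised across sessions. Independent of the package's generator (used
# as an oracle for calibration checks).
sim_chain_sessions <- function(kernel, n_sessions, len,
                               start = rep(1 / nrow(kernel), nrow(kernel))) {
  K <- nrow(kernel)
  cum <- t(apply(kernel, 1, cumsum))
  st <- matrix(0L, n_sessions, len)
  st[, 1] <- sample.int(K, n_sessions, replace = TRUE, prob = start)
  for (t in 2:len) {
    u <- stats::runif(n_sessions)
    st[, t] <- 1L + as.integer(rowSums(u > cum[st[, t - 1], , drop = FALSE]))
  }
  codes <- rownames(kernel)
  ids <- sprintf("c%05d", seq_len(n_sessions))
  tibble::tibble(
    session_id = rep(ids, each = len),
    participant_id = rep(ids, each = len),
    topic_id = 1L,
    group = NA_character_,
    step = rep(seq_len(len), n_sessions),
    activity = codes[as.integer(t(st))]
  )
}

# Transition counts via sim_chain_sessions states, tallied with base table
# (oracle route, bypassing the package's counting).
sim_chain_counts <- function(kernel, n_sessions, len) {
  s <- sim_chain_sessions(kernel, n_sessions, len)
  seqs <- split(s$activity, s$session_id)
  from <- unlist(lapply(seqs, function(x) x[-length(x)]), use.names = FALSE)
  to <- unlist(lapply(seqs, function(x) x[-1]), use.names = FALSE)
  codes <- rownames(kernel)
  tb <- table(factor(from, codes), factor(to, codes))
  m <- matrix(as.integer(tb), nrow(kernel), dimnames = dimnames(kernel))
  m
}

# Brute-force enumeration of consecutive pairs in a list of sequences.
brute_pair_counts <- function(seqs, states) {
  m <- matrix(0L, length(states), length(states),
              dimnames = list(from = states, to = states))
  for (s in seqs) {
    if (length(s) < 2) next
    for (i in seq_len(length(s) - 1)) {
      m[s[i], s[i + 1]] <- m[s[i], s[i + 1]] + 1L
    }
  }
  m
}

# Brute-force sliding-window counts.
brute_windows <- function(seqs, n) {
  out <- character()
  for (s in seqs) {
    if (length(s) < n) next
    for (i in seq_len(length(s) - n + 1)) {
      out <- c(out, paste(s[i:(i + n - 1)], collapse = "–"))
    }
  }
  table(out)
}

# The worked nine-activity example session: start at a search engine, first
# query, examine results, select a health and a general item, evaluate and
# use the first, evaluate and discard the second.
worked_example_session <- function() {
  c("Q:AccSE", "Q:NewQ", "E:ExamSR", "A:SelHI", "A:SelGI",
    "E:EvalI", "U:UseHI", "E:EvalI", "D:DisGI")
}

# Toy six-item response set for one participant x topic.
toy_responses <- function(status, participant = "p1", topic = 1L) {
  tibble::tibble(
    participant_id = participant, topic_id = topic,
    section = rep(1:3, each = 2), item_index = rep(1:2, 3),
    status = status
  )
}
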