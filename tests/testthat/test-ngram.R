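test_that("corpus splits are seeded, session-level and rounded as documented", {
  log <- simulate_corpus(n_sessions = c(L1 = 10, L2 = 0, L3 = 0), seed = 500)
  sp <- split_corpus(log, fraction = 0.8, seed = 3)
  n_tr <- dplyr::n_distinct(sp$train$session_id)
  n_te <- dplyr::n_distinct(sp$test$session_id)
  expect_equal(c(n_tr, n_te), c(8L, 2L))
  # no session straddles the split
  expect_length(intersect(sp$train$session_id, sp$test$session_id), 0)

  sp2 <- split_corpus(log, fraction = 0.8, seed = 3)
  expect_identical(sp$train$session_id, sp2$train$session_id)

  nine <- dplyr::filter(
    log, session_id %in% unique(log$session_id)[1:9]
  )
  sp9 <- split_corpus(nine, fraction = 0.8, seed = 1)
  expect_equal(dplyr::n_distinct(sp9$train$session_id), 7L) # round(7.2)

  expect_error(split_corpus(log, fraction = 1.2), "fraction")
})

test_that("Witten-Bell unigram probabilities match the closed form", {
  m <- fit_ngram(sessions_tbl(list(c("A:SelHI", "A:SelHI", "E:EvalI"))),
                 order = 1)
  # tokens predicted: A, A, B(=E:EvalI), </s>; N = 4, T = 3, V = 19
  V <- 19
  expect_equal(ngram_prob(m, character(), "A:SelHI"), (2 + 3 / V) / (4 + 3))
  expect_equal(ngram_prob(m, character(), "E:EvalI"), (1 + 3 / V) / (4 + 3))
  # unseen symbol gets exactly the reserved uniform share
  expect_equal(ngram_prob(m, character(), "Q:AccSE"), (0 + 3 / V) / (4 + 3))
})

test_that("discounting strictly reserves mass for unseen continuations", {
  # a history with a single continuation repeated c times has p < 1
  reps <- sessions_tbl(purrr::map(1:4, ~ rep(c("Q:NewQ", "E:ExamSR"), 5)))
  m <- fit_ngram(reps, order = 2)
  p <- ngram_prob(m, "Q:NewQ", "E:ExamSR")
  expect_lt(p, 1)
  expect_gt(p, 0.9)
})

test_that("conditionals sum to one over the predictable vocabulary", {
  log <- simulate_corpus(n_sessions = c(L1 = 30, L2 = 0, L3 = 0), seed = 501)
  m <- fit_ngram(log, order = 3)
  vocab <- c(activity_codes()$code, "</s>")
  seqs <- split(log$activity, log$session_id)
  set.seed(42)
  for (i in 1:25) {
    s <- seqs[[sample(length(seqs), 1)]]
    j <- sample(length(s), 1)
    h <- s[max(1, j - 2):j]
    tot <- sum(vapply(vocab, function(w) ngram_prob(m, h, w), numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-9)
  }
  # also for an unseen history (falls through to lower orders)
  tot <- sum(vapply(vocab, function(w) {
    ngram_prob(m, c("D:UnchkGI", "D:UnchkGI"), w)
  }, numeric(1)))
  expect_equal(tot, 1, tolerance = 1e-9)
})

test_that("sequence log-probability composes per-token conditionals", {
  train <- sessions_tbl(list(c("A:SelHI", "A:SelHI", "E:EvalI")))
  m <- fit_ngram(train, order = 1)
  lp <- sequence_logprob(m, c("A:SelHI", "A:SelHI", "E:EvalI"))
  pa <- ngram_prob(m, character(), "A:SelHI")
  pb <- ngram_prob(m, character(), "E:EvalI")
  pe <- ngram_prob(m, character(), "</s>")
  expect_equal(lp$logprob, 2 * log(pa) + log(pb) + log(pe))
  expect_equal(lp$tokens, 4L) # three activities + end marker
  expect_lt(lp$logprob, 0)
  expect_error(sequence_logprob(m, c("A:SelHI", "Z:Nope")), "vocabulary")
})

test_that("an empty model is the uniform model with perplexity 19", {
  u <- seekr:::.new_ngram_model(2, list(new.env(), new.env()))
  test <- sessions_tbl(list(c("Q:AccSE", "Q:NewQ", "E:ExamSR", "E:EvalI"),
                            c("A:SelHI", "E:EvalI")))
  pp <- perplexity(u, test)
  expect_equal(pp$perplexity, 19)
  expect_equal(pp$tokens, 8L)

  # a trained model beats uniform on its own repetitive corpus
  reps <- sessions_tbl(purrr::map(1:5, ~ rep(c("Q:NewQ", "E:ExamSR"), 6)))
  m <- fit_ngram(reps, order = 2)
  expect_lt(perplexity(m, reps)$perplexity, 19)
})

test_that("held-out perplexity approaches the generating entropy rate", {
  # fixed-length chains over a 3-state kernel: the per-token entropy is the
  # kernel's entropy rate up to start/end boundary terms
  kern <- matrix(c(.6, .3, .1, .2, .5, .3, .3, .2, .5), 3, byrow = TRUE,
                 dimnames = list(c3, c3))
  ev <- eigen(t(kern))
  pi <- Re(ev$vectors[, which.max(Re(ev$values))])
  pi <- pi / sum(pi)
  H <- -sum(pi * rowSums(kern * log(kern)))
  set.seed(600)
  s <- sim_chain_sessions(kern, 400, len = 200, start = pi)
  sp <- split_corpus(s, 0.8, seed = 2)
  pp <- perplexity(fit_ngram(sp$train, order = 2), sp$test)
  expect_equal(pp$perplexity, exp(H), tolerance = 0.1)
})

test_that("more training data does not hurt perplexity at the true order", {
  p <- default_profiles()$L2
  test <- simulate_sessions(p, 150, seed = 601)
  small <- simulate_sessions(p, 100, seed = 602)
  large <- dplyr::bind_rows(
    small, simulate_sessions(p, 900, seed = 603, id_prefix = "L2b")
  )
  pp_small <- perplexity(fit_ngram(small, 2), test)$perplexity
  pp_large <- perplexity(fit_ngram(large, 2), test)$perplexity
  expect_lt(pp_large, pp_small * 1.02) # tolerance for sampling noise
})

test_that("order selection is deterministic and prefers the generating order", {
  # order-1 data: no gain beyond 2-grams
  s1 <- simulate_sessions(default_profiles()$L2, 400, seed = 604)
  sel1 <- select_order(s1, orders = 2:5, seed = 5)
  expect_lte(sel1$best_order, 3L)

  sel1b <- select_order(s1, orders = 2:5, seed = 5)
  expect_identical(sel1$results, sel1b$results)

  # ties resolve to the smaller order
  fake <- sel1
  fake$results$perplexity <- rep(2, nrow(fake$results))
  best <- fake$results$order[order(fake$results$perplexity, fake$results$order)][1]
  expect_equal(best, 2L)
})

test_that("ARPA export lists every observed n-gram with its log10 probability", {
  train <- sessions_tbl(list(c("Q:AccSE", "Q:NewQ", "E:ExamSR")))
  m <- fit_ngram(train, order = 2)
  path <- withr::local_tempfile(fileext = ".arpa")
  write_arpa(m, path)
  lines <- readLines(path)
  expect_equal(lines[1], "\\data\\")
  expect_true("\\1-grams:" %in% lines)
  expect_true("\\2-grams:" %in% lines)
  expect_equal(tail(lines, 1), "\\end\\")
  # spot-check one entry against the model
  row <- grep("\tQ:AccSE Q:NewQ$", lines, value = TRUE)
  expect_length(row, 1)
  lp <- as.numeric(strsplit(row, "\t")[[1]][1])
  expect_equal(lp, log10(ngram_prob(m, "Q:AccSE", "Q:NewQ")), tolerance = 1e-5)
})
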