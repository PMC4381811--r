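# seekr

Markov and n-gram analysis of coded health information search sessions.

## The problem

Consumers searching the web for health information behave very differently
depending on how familiar they are with the health topic at hand. One way to
study this is to transcribe recorded search sessions into sequences of
*search activities* drawn from a fixed 18-code scheme spanning five stages —
querying (`Q:AccSE`, `Q:AccHW`, `Q:NewQ`, `Q:ModQ`), accessing (`A:SelHI`,
`A:SelGI`, `A:XplorF`, `A:AccB`), evaluating (`E:ExamSR`, `E:DisSR`,
`E:EvalI`, `E:FindQ`), using (`U:UseHI`, `U:UseGI`) and discarding
(`D:DisHI`, `D:DisGI`, `D:UnchkHI`, `D:UnchkGI`) — and to model those
sequences per familiarity group.

`seekr` implements that analysis pipeline end to end for researchers in
consumer health informatics and interactive information retrieval:

- **Familiarity scoring.** A 24-item health terminology questionnaire
  (3 sections × 4 topics × 2 items) is scored at 0.15 points per correct
  Section-1 item and 0.175 per correct Section-2/3 item, and each
  participant × topic is labeled L1 (points ≤ 0.3), L2 (0.3 < points ≤ 0.65)
  or L3 (points > 0.65).
- **First-order Markov transitions.** Per group, the transition count matrix
  `f_ij` over the 18 states and its row-normalised kernel
  `p_ij = f_ij / Σ_j f_ij`, with ranked top-k transition reports.
- **Chi-square comparison of groups.** For samples A (reference) and B
  (tested), expected counts `E_ij = n_i(B) · p_ij(A)` and the Pearson-type
  score `C = Σ (f_ij(B) − E_ij)² / E_ij`, referred to a chi-square
  distribution with `df = K² − N₁ − N₂` (K states, N₁ actual states in B,
  N₂ impossible transitions).
- **N-gram language models.** Orders 2–7 with interpolated Witten-Bell
  discounting over the closed 18-code vocabulary plus boundary markers;
  the order is selected by held-out perplexity
  `PP = exp(−Σ log p(w_k | h_k) / t)` on a seeded 80/20 session split.
- **Pattern mining.** Contiguous length-n activity windows per group, top-20
  tables, and rule-based tags for four behavioural categories
  (query→single-access→evaluate, query→multiple access, relevancy
  assessment, continuing after success).
- **Synthetic data.** A seeded generator of labeled session corpora and
  questionnaires whose kernels are anchored on the published per-group
  top-10 transition shares, so the full pipeline is testable without the
  original video transcripts.

Everything takes and returns tidy tibbles, chains with the pipe, and
supports `tidy()`, `glance()` and `autoplot()` on its result objects.

## Worked example

```r
library(seekr)
library(dplyr)

log <- simulate_corpus(n_sessions = 200, seed = 42)   # 200 sessions per group

search_efficiency(log)
#>   group n_use n_access efficiency
#> 1 L1      556     1254      0.443
#> 2 L2      753     1346      0.559
#> 3 L3      683     1391      0.491

top_transitions(group_transition_matrices(log)$L1, k = 5)
#>    rank from     to           n share_pct
#> 1     1 A:SelHI  E:EvalI    434      7.90
#> 2     2 E:ExamSR A:SelHI    430      7.83
#> 3     3 E:EvalI  D:DisHI    338      6.15
#> 4     4 Q:ModQ   E:ExamSR   262      4.77
#> 5     5 E:EvalI  U:UseHI    238      4.33

compare_groups(log, "L1", "L3")
#> Chi-square comparison of transition matrices (L1 vs L3)
#>   C = 2818.487 on df = 302 (K^2 = 324, N1 = 18, N2 = 4)
#>   critical value 383.677 at alpha = 0.001 -> reject H0
#>   (direction BA: L1 tested against L3)

select_order(log, orders = 2:7, seed = 42)$best_order
#> [1] 2    # the generator is a first-order chain, so 2-grams suffice

pattern_summary(log, n = 5, k = 20)$tables$L1[1:3, 1:4]
#>    rank pattern                                       n share_pct
#> 1     1 Q:AccSE–Q:ModQ–E:ExamSR–A:SelHI–E:EvalI      47     0.960
#> 2     2 E:ExamSR–A:SelHI–E:EvalI–A:XplorF–E:EvalI    37     0.756
#> 3     3 Q:ModQ–E:ExamSR–A:SelHI–E:EvalI–D:DisHI      32     0.654
```

Reading the output: the unfamiliar (L1) profile turns fewer accessed items
into used sources than L2/L3; its most frequent transitions and its modal
5-activity pattern revolve around reformulating queries and evaluating (and
often discarding) health pages. The perplexity sweep picks the smallest
order consistent with the data — order 2 here, because the synthetic corpus
really is first-order; sequences with genuine higher-order structure (see
`motif_profile()`) select accordingly.

`run_pipeline()` chains all stages (optionally starting from a
questionnaire table) and returns the full report bundle with a manifest.

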