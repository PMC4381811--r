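---
title: "Models and methods behind seekr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind seekr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(seekr)
```

`seekr` analyses health information search behaviour recorded as sequences
of coded search activities. This vignette documents the statistical models,
the conventions and tunable parameters, the design decisions taken where the
methodology left choices open, and what the synthetic-data generator does
and does not emulate.

## Data model

A *session* is one participant working on one health topic, transcribed as
an ordered sequence of activities from a closed 18-code alphabet in five
stages (querying, accessing, evaluating, using, discarding). Everything in
the package operates on a long-format tibble with one row per activity
(`session_id`, `participant_id`, `topic_id`, `group`, `step`, `activity`).

Codes are canonical strings (`"E:EvalI"`, not `"e:evali"`); validation
rejects near-misses rather than normalising them, so transcription errors
surface instead of silently merging states. Sessions with any violation
(unknown code, non-consecutive steps, emptiness) are excluded from all
statistics and reported, mirroring the restriction of such analyses to
qualified transcripts.

## Familiarity scoring

The questionnaire has three sections covering the same four topics, two
items per section × topic. Section 1 probes surface recognition; sections 2
and 3 probe conceptual understanding of consumer-friendly and advanced
terminology. Correct answers earn 0.15 (section 1) or 0.175 (sections 2–3)
points; the six items of a topic can thus reach exactly 1.0. Labels: L1 for
points ≤ 0.3, L2 for (0.3, 0.65], L3 above.

Numerical choices:

* Points are multiples of 0.005, so they are held internally as integers on
  a 1/200 scale. The threshold comparisons at 0.3 and 0.65 are therefore
  exact; no floating-point boundary misclassification is possible.
* `"unknown"` scores 0, identical to `"incorrect"`: respondents are
  instructed not to guess, and points attach only to correct answers.
* The two-items-per-section×topic layout is enforced; incomplete or
  duplicated questionnaires are rejected with the offending slot named,
  never imputed.

## Transition matrices

Per group, the first-order transition count matrix `f[i, j]` tallies every
within-session move; transitions never cross session boundaries, so a
session of length `L` contributes `L − 1` counts. Probabilities are
row-normalised; rows with zero total stay all-zero rather than being set to
uniform — the comparison test accounts for the resulting structural zeros
explicitly.

Ranked reports (`top_transitions()`) break frequency ties by (from, to)
lexicographic order on the canonical code strings, so output is
deterministic. `mean_transition_stats()` summarises the counts of ordered
pairs observed at least once; its standard deviation uses the population
denominator, recorded in the output so the convention is auditable.

## Chi-square comparison of two groups

The comparison treats sample A as the reference and sample B as tested:

* expected counts `E[i, j] = n_i(B) · p[i, j](A)`, i.e. B's row totals
  redistributed under A's kernel;
* score `C = Σ (f[i, j](B) − E[i, j])² / E[i, j]` over cells with positive
  expectation;
* reference distribution chi-square with `df = K² − N₁ − N₂`, where `K` is
  the state-space size, `N₁` the number of states actually occurring in B
  (as source or destination of a transition), and `N₂` the number of
  impossible transitions — zero-expectation cells within rows B occupies.
  Cells of rows B never occupies are excluded without entering `N₂`; the
  accounting identity `cells_used + N₂ + 18·(unoccupied rows) = K²` is
  unit-tested.

Design decisions:

* **Direction.** The procedure is asymmetric and the methodology does not
  fix a direction, so `compare_transition_matrices()` computes both and
  reports the larger-C direction by default; a single direction can be
  requested (`direction = "AB"`).
* **Significance level.** The default is `alpha = 0.001`; the critical
  values at df 64 and 60 quoted for this analysis (104.716, 99.607)
  correspond to the 0.001 upper tail. `alpha` is an argument, not a
  constant.
* **Calibration regime.** The chi-square reference treats A's kernel as
  known. When both samples are of comparable size, the extra variance from
  estimating A inflates C (roughly by `1 + n_B/n_A` per degree of freedom)
  and the test becomes anticonservative: two same-kernel samples of equal
  size will usually "differ". The package therefore documents — and its
  tests verify — calibration in the regime where the reference sample is
  large relative to the tested one (the type-I check uses 50,000 reference
  vs 2,000 tested transitions on a 3-state kernel, 1,000 seeded
  replicates). Interpret equal-size comparisons as descriptive effect
  sizes, not calibrated tests. Cells with very small expectations add
  further skew; with the 18-state space this matters below roughly 5
  expected counts per cell.

## N-gram models and perplexity

Models of order `n` are trained on sessions padded with `n − 1` start
markers and one end marker. Start markers are never predicted; the end
marker is predicted and counted, so the predictable vocabulary is the 18
codes plus the end marker (19 symbols) and a session of length `L`
contributes `L + 1` scored tokens. The vocabulary is closed — the coding
scheme fixes the alphabet — so there is no unknown-word state and
out-of-vocabulary codes are an error.

Smoothing is *interpolated* Witten-Bell: with `c(h, w)` the continuation
count, `c(h) = Σ_w c(h, w)` and `T(h)` the number of distinct symbols seen
after history `h`,

```
p(w | h) = (c(h, w) + T(h) · p(w | h′)) / (c(h) + T(h))
```

where `h′` drops the oldest symbol; unseen histories fall through to the
lower order, and the order-0 base is uniform over the predictable
vocabulary. The toolkit family this follows supports both backoff and
interpolated variants; the interpolated form was chosen and is recorded in
the model metadata. Conditionals provably sum to 1 for every history, and
an untrained model is exactly the uniform model with perplexity 19 — both
are property-tested.

Perplexity pools log-probability over sessions:
`PP = exp(−Σ logprob / Σ tokens)`. `select_order()` makes one seeded
*session-level* 80/20 split (a session is the natural sentence unit; the
training share is `round(0.8 · n)` sessions), evaluates each candidate
order on the shared split, and returns the argmin with ties resolved to the
smaller order. Order range 2–7 is the default sweep.

Serialisation (`write_arpa()`) writes observed n-grams with base-10 log
probabilities in the standard `\data\` / `\n-grams:` layout; because the
model interpolates at query time, final probabilities are written and no
back-off weight column is included.

## Pattern mining and behavioural categories

Pattern windows are contiguous, *unpadded* length-n subsequences — mined
patterns consist solely of activity codes, unlike the language models. A
session of length `L` contributes `max(0, L − n + 1)` windows; shares use
token windows as denominator, with the distinct-type count reported
alongside. Top-k tables default to `k = 20`, the depth beyond which pattern
frequencies are too low to characterise a group.

The four behavioural categories are narrative in origin; the package
formalises them as an explicit, versioned rule set (v1):

1. a querying prefix (entry at `Q:AccSE`/`Q:AccHW` immediately followed by
   `Q:NewQ`/`Q:ModQ`) followed in the window by exactly one `A:SelHI` and a
   later `E:EvalI`;
2. a querying prefix followed by a run of ≥ 2 consecutive selections
   (`A:SelHI`/`A:SelGI`);
3. `E:EvalI` immediately followed by a use/discard assessment
   (`U:UseHI`, `U:UseGI`, `D:DisHI`, `D:DisGI`);
4. a use activity followed later in the window by a querying-stage activity
   or `E:ExamSR`.

A pattern may match several categories; tags are deterministic given the
rule-set version, so alternative readings of the narrative definitions can
be configured as new versions without breaking reproducibility.

## The synthetic-data generator

The study's raw transcripts are unpublished, so the generator produces
corpora with the statistical structure the analysis assumes. It is
first-class, tested code — not a fixture.

**Kernels.** Each group's 18×18 kernel is a pseudo-count mixture: the
published per-group top-10 transition counts are placed on their cells, and
the remaining mass (relative to the published group transition totals) is
spread over unanchored cells proportionally to destination-state weights
whose shape follows the reported activity mix (evaluating > accessing >
querying > using/discarding). Two calibration notes: the weight floor (4)
keeps every state's stationary share large enough that kernel-recovery
checks on simulated corpora are statistically meaningful, and for L3 the
query-reformulation weight is lowered, reflecting that familiar searchers
reformulate less. These kernels are calibration anchors, not estimates of
the unpublished full matrices.

**Starts and stops.** Sessions start at a general search engine, with the
familiar group placing 0.30 probability (L2: 0.05; L1: 0) on starting
directly at a consumer health website. Sessions end after an
information-use activity (`U:UseHI`/`U:UseGI`) with a per-group stop
probability, never before length 6 and forced at 221 — so every simulated
session contains a use activity and ends in the using stage ("successful
session" mode), with the hard-truncation caveat at the maximum length. The
stop probabilities (L1 0.4061, L2 0.2843, L3 0.2943) were calibrated
numerically — bisection on simulated corpora of 200,000 sessions — to hit
the mean session length target of 28.7 activities; the groups need
different values because their kernels visit use-stage states at different
rates. The standard deviation is emergent rather than separately tuned and
comes out near the 23.27 target.

**Questionnaires.** Per-label, per-section correctness probabilities (L1
recognises some surface terminology; L2 also masters consumer-friendly
terminology; L3 additionally advanced terminology) are set so that scoring
a simulated questionnaire recovers the requested label ≥ 95% of the time;
the closed loop through `score_familiarity()` is tested.

**Higher-order ground truth.** `motif_profile()` builds a history-keyed
kernel that repeats an activity motif and, with probability `noise`
(default 0.1), emits a dedicated restart activity after which the motif
restarts. The restart pins the phase, so the process is an *exact* Markov
chain of the motif's history length; with a motif whose 4-windows are
unique but whose 3-windows are ambiguous, a 5-gram model is the smallest
adequate order, which the order-selection check verifies. (An earlier
design that flipped motif symbols in place was discarded: resynchronising
after an in-alphabet flip genuinely requires more history than the motif
order, which contaminated the ground truth.)

**Determinism.** All generators take integer seeds and use R's default
Mersenne-Twister stream via scoped seeding, so a fixed seed yields a
byte-identical corpus; corpus manifests record the seed, sizes and a kernel
fingerprint.

**What the generator does not emulate.** Real sessions exhibit
participant-level heterogeneity, topic effects, time-varying behaviour and
genuine higher-order structure; the default profiles are homogeneous
first-order chains anchored only on printed top-10 cells. Published
group-level quantities that depend on the unpublished full data — the
comparison C statistics, absolute perplexity values, label counts, the
4595-activity total, the search-efficiency percentages — are consequently
*not* reproduction targets; passing tests demonstrate correctness of the
pipeline's operations and calibration of its statistics on data whose
generating process is known, not agreement with the original cohort.

## Problem sizes and runtimes in the checks

The property suite uses sizes chosen to make each check statistically
informative while keeping the whole suite quick: 1,000 seeded replicates
for the type-I calibration of the comparison (3-state kernel, 50,000
reference / 2,000 tested transitions each); 50,000 sessions for kernel
recovery (max-abs deviation < 0.01); 100 random histories for Witten-Bell
normalisation; 120 motif sessions for order selection; 40 replicates of a
20,000-vs-500-session same-kernel comparison for the null rejection rate.

## Known limitations

* The chi-square comparison is only calibrated with a large reference
  sample; no finite-sample correction (e.g. permutation nulls) is
  implemented beyond what the tests use as cross-checks.
* `mean_transition_stats()` and the ranked reports describe observed cells
  only; structural zeros are invisible to them by design.
* The ARPA export omits back-off weights (probabilities are final), so
  third-party readers that insist on back-off semantics will treat unlisted
  n-grams slightly differently than this package does.
* Category rules are one formalisation (v1) of narrative definitions;
  alternative readings belong in new rule-set versions.
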