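---
title: "Methods: semi-automatic occupational coding and exposure assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-automatic occupational coding and exposure assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occucode)
```

## The problem

Epidemiological cohorts collect occupational histories as free text:
answers to open questions about one's occupation, tasks, employer,
sector. Before a job-exposure matrix (JEM) can convert those histories
into exposure estimates, every episode must carry a standardized code
from a hierarchical classification — occupation systems such as ISCO-88
(4 digit levels) or PCS (3 digits + letter) and activity-sector systems
such as NAF (4 digits + letter, with a 21-section grouping above the
2-digit division). Manual coding is slow and expert coders agree with
each other only moderately (κ typically 0.4–0.8 depending on depth), so a
useful system does not replace the coder: it suggests complete codes with
a calibrated confidence score, auto-codes the easy cases above a
threshold, and leaves the rest for review with a ranked short-list.

`occucode` implements that workflow end to end, plus the statistics
needed to evaluate it: per-level accuracy and Cohen's κ, human-vs-model
comparison, and four JEM evaluation protocols.

## Codes and schemes

A scheme (`scheme_spec()`) fixes the significant length of a code, which
prefixes constitute the coding levels, the canonical separators (the
`1-21.10` rendering), the placeholder character for positions an expert
could not code (`#`), and a per-position alphabet. Codes shorter than the
full length are right-padded with placeholders on parse, following the
convention of datasets that record only the codable levels (`1-21` for
`1-21.##`). An episode is *viable* for training only when its gold code
is complete — the coder must be able to suggest complete codes.

Two open points in the shipped approximate schemes were decided as
follows. The PCS letter is taken to complete only the deepest level
(digits define levels 1–3); nothing in the level structure of published
per-level results contradicts either reading, and this one keeps levels
1–3 purely numeric. The NAF level-1 section is realized as a lookup table
from the 2-digit division using the public 21-section grouping; an
unmapped division falls back to the raw prefix rather than erroring, so
user-extended schemes degrade gracefully.

## Text preparation and embedding

Descriptions are tokenized, punctuation-stripped, lower-cased and stemmed
(English Snowball; implemented in R because no stemmer ships with the
target stack, and verified token-for-token against the reference
implementation on a frozen vocabulary). Each input class of an episode is
embedded separately and the vectors are **summed**, which makes fusion
order-independent and a missing class a no-op.

The default embedder is a deterministic hashed bag-of-stems: every token
is hashed into **two** buckets of a `dim`-length vector (default 256) by
independent FNV-1a hashes, each contribution carrying a pseudo-random
sign. Design notes:

- Signed hashing keeps disjoint vocabularies orthogonal in expectation.
- The second hash matters: with a single hash at desk-scale dimensions a
  non-negligible share of tokens receives an *identical* (bucket, sign)
  signature — such tokens are mathematically indistinguishable downstream
  and cap the accuracy of any classifier. Two buckets make full-signature
  collisions vanishingly rare while leaving cost unchanged.
- Pretrained sentence embedders can be plugged in via
  `custom_embedder()`. They receive raw text, not stems: stemming
  degrades models trained on surface forms. Whether the original
  production systems stem before pretrained embedding is unknowable from
  the published description; the two shipped paths make either choice
  explicit rather than guessing.

## The coder

The classifier is a multiclass gradient-boosted ensemble of CARTs
(one binary ensemble per class on the softmax objective, exact greedy
splits, second-order gains), implemented in `src/gbt.cpp`. It supports
the regularization surface of mainstream boosting libraries, and the
defaults are the fixed, pre-published setting used for every model —
deliberately not tuned per dataset:

| parameter | default | meaning |
|---|---|---|
| `eta` | 0.6 | learning rate on leaf weights |
| `max_delta_step` | 1 | cap on absolute leaf weight |
| `max_depth` | 20 | maximum tree depth |
| `gamma` | 1.5 | minimum loss reduction to split |
| `lambda` | 1e-4 | L2 penalty on leaf weights |
| `min_child_weight` | 0 | minimum hessian sum per child |
| `subsample` | 0.75 | row sampling per tree |
| `colsample_bytree/bylevel` | 1 | column sampling |
| `early_stopping_rounds` | 1 | patience on validation loss |

Early stopping monitors validation multiclass log-loss (the monitored
metric is not pinned down by the published description; log-loss is this
implementation's documented choice, recorded in the model metadata) with
a 500-round cap that early stopping never reaches in practice. Training
randomness (row/column subsampling) comes from a private xorshift stream
seeded from `coder_params(seed=)`, so training is bit-reproducible across
platforms regardless of R's RNG state. Class imbalance is left untouched
by design: minority classes of size 1 admit no synthetic oversampling,
and undersampling would discard most of the majority information.

Data flow: viable episodes are split 60/30/10 into train/test/validation
(largest-remainder rounding, seeded permutation); the training partition
is augmented with the coding index (one canonical description per code),
which makes every code of the classification a trainable class; training
uses the training partition only, validation only for stopping, test only
for reported metrics. Per-level metrics truncate the predictions of the
single full-depth model — there are no per-level models — so accuracy is
non-increasing in level by construction.

`select_input_classes()` is the exhaustive wrapper: one model per
non-empty subset of candidate input classes, scored on test accuracy,
ties resolved toward fewer classes then lexicographically. It refuses
more than 6 candidates (64 models) rather than silently running for
hours.

## Decision support

Confidences are the softmax class probabilities. Routing sends a record
to the auto-coded queue when its rank-1 confidence is **at or above** the
threshold (the published description says "above" loosely; the inclusive
convention is documented in the CLI help and here). Binning uses twenty
5-point bins, lower-inclusive, top bin `[95,100]` closed. The minimum
workload reduction is `fraction_above × accuracy_above / 100`, reported
to one decimal: auto-coded-and-correct records leave the expert's queue;
auto-coded-but-wrong ones still cost correction, hence "minimum".

## Evaluation statistics

Accuracy is exact string equality of canonical codes (or level labels),
times 100. Cohen's κ is `(P_o − P_e)/(1 − P_e)` with `P_e` the sum over
labels of the product of the two coders' marginal proportions; when both
coders use a single identical label (`P_e = 1`) the function returns
exactly 1, and two different constant labels give κ = 0. The test suite
checks κ against a brute-force `P_o`/`P_e` oracle to 1e-12.

The human-vs-model comparison takes per-pair expert κ values and
per-model κ values by level: Shapiro–Wilk per group, classic Levene
(one-way ANOVA on absolute deviations from group means — the `car`-style
default; no Brown–Forsythe median variant, since normality is asserted
first) across groups, then a pooled t-test (`df = n1 + n2 − 2`) when
Levene does not reject at α = 0.05 and Welch otherwise. Sample SDs use
n−1 — the published level-3 SD of 0.08 for four model κs reproduces only
under n−1. Hedges g uses the pooled SD and the small-sample correction
`1 − 3/(4(n1+n2) − 9)`; it is reported but carries a caveat: published
g values of this form are not reproducible from the printed summary
statistics, so no equality claim is made against them.

## JEM evaluation

**Continuous matrices** map an occupation code (optionally an
occupation–sector pair, optionally per calendar period) to probability
(% of workers exposed), intensity (mean dose, arbitrary units) and
frequency (% of working time). Total exposure is their product with the
percentages as proportions; an episode is *exposed* iff the total is
strictly positive. The evaluation compares totals derived from gold vs
predicted codes: exact-match accuracy (well-defined because totals come
from a finite lookup table — no tolerance is needed or defined), κ with
each distinct total as a category (the categorical κ definition is this
package's documented reading; whether the original analyses binned
exposures first is unknown), dichotomous accuracy/κ, and tie-corrected
Kendall τ_b with a normal-approximation two-sided p — τ_b because totals
are massively tied at zero. Every metric is computed for all episodes and
for the gold-exposed subset, which counters the high chance agreement of
all-zero assignments. With two codes per episode the confidence used for
binning is the **minimum** of the two codes' confidences, mirroring an
auto-coding rule that requires both codes to clear the threshold.

**Ordinal matrices** map an occupation code to a 0/1/2 level per agent.
An episode's assessment is correct only if *every* agent level matches;
per-agent accuracy/κ and per-level accuracy within each agent complete
the picture, again for all and for exposed (any gold agent > 0) episodes.

A predicted code absent from a matrix yields zero exposure under the
default policy and increments a reported unmatched counter (`strict`
errors instead); the original behaviour for unmatched codes is not
documented anywhere, and zero-with-counter keeps the evaluation total
while making the information loss visible.

## Synthetic data: what it emulates, and what a green test proves

The generator reproduces the structural features that make this problem
hard: very short texts (per-class word counts `1 + Poisson(median − 1)`,
targeting the observed medians of 1–3), bounded-Zipf class imbalance
(exponent 1 by default, reproducing the singleton-to-huge-class shape;
0 gives near-balance), placeholder-incomplete gold codes (5 % by
default), per-code private vocabularies with a shared noise vocabulary
(noise rate 0.1 by default), a coding index with one clean description
per code, and JEMs in which only a small fraction of codes (10 % by
default) carries non-zero exposure. Tokens are abstract alphanumerics
ending in a digit, so stemming is the identity on them by construction.

It does **not** emulate natural language: no synonymy, no morphology, no
cross-class vocabulary sharing, no translation noise, and no model of
human coder disagreement. A green recovery test therefore establishes
that the pipeline's plumbing and statistics are correct — not that the
coder reaches any particular accuracy on real cohort text.

### The clean recovery world and the gamma-at-scale effect

`recovery_corpus_spec()` pins the configuration used for end-to-end
recovery checks: 20 codes × 50 examples, noise 0, balanced, fully coded,
**2 tokens per code per input class**, seed 1. The compact vocabulary is
deliberate and worth explaining, because it interacts with a fixed
hyperparameter. `gamma = 1.5` is an *absolute* loss-reduction threshold:
a split isolating the examples of class *k* has second-order gain of
roughly `n_k (1 − p) / (4 p)` at class probability `p`, so with the
hundreds-to-thousands of examples per class of production corpora gamma
never binds, while at desk scale it prunes the split for any token with
too few occurrences and caps the achievable class probability near
`n_k / (n_k + 4γ)`. Two consequences, verified against a reference
boosting implementation during development:

- a clean world whose classes spread over many rare tokens is *not*
  mastered at 50 examples/class even though it is perfectly separable —
  each token must carry enough support for its split to clear gamma;
- confidences cannot reach 0.95 at this scale (that needs roughly 115+
  examples per class), so the `[95,100]` confidence bin is empty in the
  recovery run. The calibration check therefore also asserts the
  non-vacuous form — the highest *occupied* bin's accuracy is at least
  the overall accuracy — rather than relying on a vacuously true bound.

The realistic-world defaults (`vocab_per_code = 6`, noise 0.1, Zipf
imbalance 1) predate this analysis and were left unchanged; they describe
data the coder is *not* expected to master perfectly, which is exactly
what the confidence-threshold machinery is for.

## Numerical conventions and degenerate inputs

- Bin index: `floor(20 · confidence + 1e-9)`, capped at bin 20; the
  epsilon guards values like 0.35 whose product lands one ulp below an
  integer.
- Suggestion ties: equal probabilities rank by label-table order, so
  suggestion lists are total and reproducible.
- Kendall τ on a constant margin is undefined and raised as an error by
  `kendall_tau()`; inside `evaluate_continuous()` a constant side (e.g. an
  all-zero matrix) reports `NA` rather than failing the whole report.
- Model bundles store tree thresholds and leaf weights as
  17-significant-digit strings inside JSON; plain JSON number rounding
  breaks the bitwise save/load contract.
- Shapiro–Wilk needs n ≥ 3 and non-constant data; smaller or constant
  groups report `NA` for it while the rest of the comparison proceeds.
- `split_dataset()` errors when records cannot fill all three partitions;
  `train_coder()` errors on single-class data and on an empty validation
  set rather than silently skipping early stopping.

## Known limitations

- The shipped schemes approximate level *structure* only; they carry no
  official nomenclature titles and no crosswalks between schemes.
- The English stemmer is the only built-in normalizer; French and Dutch
  text passes through unstemmed (`language = "none"`), which matches the
  embedding path for pretrained models but not a production French
  pipeline.
- Calendar-period resolution in JEMs supports a single query year; career
  aggregation across episodes and periods is out of scope.
- Hedges g is reported with the standard correction but not validated
  against published values (see above).
- The boosted-tree coder is a faithful desk-scale reimplementation, not a
  tuned production model; with the fixed hyperparameters its confidence
  scale at small n is compressed (see the gamma analysis), so thresholds
  near 0.95 are only meaningful at production data sizes.
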