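---
title: "Building claims cohort definitions from masked code summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building claims cohort definitions from masked code summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(claimdef)
```

## The problem and the model

Administrative claims studies define cohorts by procedure and diagnosis
codes. When the claims sit in a secure enclave, the people who understand
the clinical question usually cannot browse the data, and the analyst who
can cannot easily show them what a candidate definition captures or
misses. `claimdef` addresses this with a two-stage design: a summarization
stage that runs against the claims and emits only a small,
disclosure-controlled table, and a counting stage that needs nothing but
that table.

The summarization stage rests on one premise: for a given service there
exist diagnosis codes genuinely tied to it (indications, findings,
complications), mixed in among codes that are merely common (chronic
comorbidities) or that track the demographics of the treated population.
Three mechanisms separate them:

* **Matching** (`match_controls()`) pairs each sampled service claim with
  a non-service claim from the same setting, exactly on sex and on the
  number of recorded diagnosis codes, and as close as possible on age.
  Codes whose prevalence is driven by age, sex or coding intensity then
  appear at similar rates in both arms and stop looking service-specific.
* **The classification tree** (`fit_tree()`) works on binary
  presence/absence indicators of 4-character code stems and ranks codes by
  how much label entropy their splits remove. Unlike a frequency table, it
  surfaces codes that are *distinctive* of service claims regardless of how
  rare they are.
* **The proportion-interval screen** (`screen_codes()`) keeps only codes
  credibly *more* frequent in service claims: each arm's carrier proportion
  gets a beta distribution with shapes `1 + p*n` and `1 + n - p*n`, and the
  code survives only if the interval between the service arm's 5th and 95th
  beta percentiles lies strictly above the control arm's.

The surviving codes, in importance order, partition the service sample
into groups (first group: claims with the top code; second: remaining
claims with the next code; and so on). The group-by-code count table —
after masking every count under 11 to the range [1, 10] — is the only
artifact that leaves the enclave. The counting stage
(`apply_selection()`) turns include/exclude selections over codes into
interval cohort counts by replacing masked values with their extremes,
flooring at zero, and reporting the total interval width as the "maybe"
mass that masking makes unattributable.

## Parameters that matter

| parameter | default | meaning and rationale |
|---|---|---|
| `min_age` | 65 years | Medicare-style population restriction applied to both arms. |
| `train_max`, `valid_max` | 5000, 1000 claims | training/validation sample caps; smaller cohorts are used whole and split 5:1, remainder (half-up) to training, so validation metrics exist even for small services. |
| `interval_quantiles` | 0.05, 0.95 | beta quantile levels of the screen. The documented worked bounds (16.40–19.82% for 246/1364; 0.49–0.51 and 0.017–0.024 at n = 5000) are reproduced by the 5th/95th percentiles, not by 2.5th/97.5th, so that convention is the default; `c(0.025, 0.975)` is available. |
| `max_depth` | 75 | effectively unbounded for feature tables of this size; the goal is surfacing candidate codes, not generalization. |
| `prune` | off | C4.5-style pessimistic pruning (subtree replacement, confidence factor 0.25) exists for experiments, but pruning removes exactly the rare edge-case codes the workflow is designed to catch. |
| `mask_threshold` | 11 claims | disclosure rule: counts of 10 or fewer leave the enclave only as [1, 10]. |

## Numerical and tie-break conventions

* Entropy is measured in bits; the base cancels in every argmax.
* Split ties (equal gain, to 1e-12) go to the lexicographically smallest
  code, making fits independent of column and input order.
* Leaf predictions are majority votes with ties predicting *control* —
  deterministic and conservative for sensitivity.
* A node stops splitting when pure, when no code varies within it, when
  the best gain is non-positive, or at `max_depth`.
* Degenerate inputs fail loudly: single-class training labels, empty
  eligible cohorts and empty control pools are errors, not silent results.
* Percentages are reported half-up at 2 decimals (whole percents in count
  summaries); half-up matches how such tables are conventionally printed,
  whereas R's `round()` is round-half-even.
* Matching processes service claims in seeded random order; age ties are
  broken by a seeded draw, so a (data, seed) pair reproduces byte-identical
  artifacts end to end.
* Zero cells are omitted from masked tables rather than masked: emitting
  [1, 10] for an empty cell would assert a carrier that does not exist and
  break the soundness guarantee that true counts always lie inside emitted
  ranges.

## Design choices where the design was open

* **Matching algorithm.** Greedy 1:1 nearest-neighbour without
  replacement, exact on sex and dx count with stepwise widening to ±3 only
  when no exact dx-count candidate remains. Simple, deterministic, and on
  generator data it achieves mean |Δage| under 0.1 years with zero
  unmatched claims; optimal matching would buy nothing here.
* **Exact-age vs binned-age matching.** Exact nearest age was chosen; with
  pools an order of magnitude larger than samples the achieved age balance
  makes binning moot.
* **Claims, not patients, are the unit.** One patient may contribute
  several claims; the summarization describes service *encounters*.
* **Importance statistic.** Claim-weighted entropy reduction, normalized
  to max 1. Any reasonable impurity-based importance preserves the only
  property downstream stages rely on: positive iff the code is used in a
  split.
* **Interval-sum counting.** Included/excluded totals are straight sums of
  per-code total ranges, so a claim carrying two selected codes is counted
  under both. The engine's output is deliberately labelled an *estimated
  claim count*; deduplicated counting is impossible from a masked marginal
  table, and the group structure (each claim belongs to exactly one group)
  keeps the duplication visible in the cells.
* **"Maybe" mass.** Defined as the sum of the included and excluded
  interval widths — exactly the claim mass that masked cells prevent from
  being attributed to either side — and reported against the tabulated
  sample size.

## What the synthetic generator does and does not emulate

`sim_truth_default()` describes 50,000 carrier claims: ages skewed over 65
(9% disability-entitlement under-65s), 55% female, per-claim diagnosis
counts following a shifted negative binomial with mean 8 (capped at 25
slots), 10 planted indication codes configured at 10-fold service
enrichment, 4 confounder codes riding on age/sex/dx-count, 20
equal-prevalence background comorbidities, and a 240-code Zipf-weighted
filler pool (~270 distinct codes overall). Service status is generated
*from* indication presence through a logistic link whose per-code
coefficients are the log odds ratios implied by the configured arm
prevalences, with the intercept calibrated by root-finding to the target
service rate; demographic terms in the same model create the confounding
that matching must remove.

Two honest caveats. First, because the link spreads service probability
across correlated causes, realized arm-prevalence ratios are attenuated
relative to the configured 10-fold (roughly 3–5-fold in generated data);
the screen detects them comfortably at the default sample sizes, and
`truth_report()` states expectations from the configured truth. Second,
real claims have hierarchically related codes, longitudinal patient
structure, cost fields and setting-specific coding practices, none of
which are emulated — passing recovery tests shows the pipeline recovers
the generating structure it was given, not that any particular clinical
service will separate as cleanly.

## The screen's false-retention rate

The interval-overlap rule is not a hypothesis test with a controlled
error rate. For a code with identical true prevalence in both arms, the
probability that sampling noise alone pushes the service interval
strictly above the control interval can be computed exactly by
enumerating both binomial counts:

```{r}
false_retention <- function(p, n) {
  ks <- 0:n
  pk <- dbinom(ks, n, p)
  lo <- qbeta(0.05, 1 + ks, 1 + n - ks)
  hi <- qbeta(0.95, 1 + ks, 1 + n - ks)
  sum(vapply(which(pk > 1e-12), function(kc) {
    pk[kc] * sum(pk[lo > hi[kc]])
  }, numeric(1)))
}
false_retention(0.2, 5000)
false_retention(0.02, 5000)
```

Both are about 1% per code, essentially independent of prevalence. With
tens of equal-prevalence background codes and repeated runs, occasional
false retentions are therefore *expected*: across the test suite's
20-seed recovery experiment (20 background codes, 5,000 claims per arm)
the expected number of escapes is on the order of a few, and the suite's
strict zero-escapes assertion documents this property honestly rather
than hiding it. Practically: a definition builder should treat a
low-importance retained code with near-touching intervals as a candidate
for manual review, not as ground truth.

## Problem sizes used by the tests

Module tests run on generated populations of 1,000–12,000 claims with
matched samples of 100–1,000 per arm — large enough for the balance and
recovery properties to be sharp, small enough to keep the suite quick.
The end-to-end recovery experiment uses the default 50,000-claim
population with 5,000 claims per arm over seeds 1–20. The exhaustive
oracles (tree root splits, grouping by set subtraction) run on instances
of at most 12 claims and 4 codes, where enumeration is trivially exact.

## Known limitations

* Counts are claim counts, not patient counts, and selected-code sums
  double-count multi-code claims (see above).
* The screen applies no multiple-testing correction; its per-code
  false-retention rate is the price of keeping rare true indications.
* Diagnosis lookback windows (codes recorded on *earlier* claims) are out
  of scope; the summary reflects codes on the service claim itself.
* Code validity against official ICD-10-CM/CPT lists is not checked;
  4-character truncation is assumed meaningful for the coding system used.
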