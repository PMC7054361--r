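---
title: "Quantifying individual left/right motor bias: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying individual left/right motor bias: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turnbias)
```

## The scientific problem

Larval zebrafish deprived of visual input circle persistently in one
direction, and individual larvae keep a preferred direction across repeated
trials and across days — an individual left/right *motor identity*. Because
the population is balanced (similar numbers of left- and right-biased
animals), population averages hide the effect entirely; the statistical
problem is to decide whether *individuals* are biased, against a null in
which every animal picks directions at random.

Two features make this harder than a textbook binomial test:

1. **Sequential persistence.** Consecutive routine turns are not
   independent — a turn tends to repeat the direction of the previous one
   ("locking"). Any null model that ignores this wildly understates the
   spread of per-animal direction preferences.
2. **Heavy trial filtering.** Trials with too little tracking data or too
   few turns are excluded, so test statistics must be built on exactly the
   records that survive the filters.

`turnbias` implements the full inferential chain: per-larva bias metrics,
a Markov-chain Monte-Carlo null model, a one-sample permutation test of
direction persistence, calcium-imaging responder classification, and the
accompanying effect sizes, plus seeded synthetic-data generators so that
every stage is testable without raw tracking data.

## Bias metrics

For trajectory data, the **net turn angle** (NTA) of a trial is the signed
sum of all path direction changes over the 30-s recording window
(rightward positive); the **absolute NTA** sums unsigned changes and
measures total turning. Trials contributing less than 10 s of data are
invalid. Because tracking dropouts can leave sparse samples spread across
the whole window, `compute_nta()` estimates the data span as
*sample count × median inter-sample interval* rather than the raw time
range; a series that nominally spans 30 s but contains 5 s of samples is
excluded.

The **Match Index** (MI) of a four-trial larva is the fraction of trials
2–4 whose NTA sign matches trial 1. Under no individual bias its
expectation is 0.5. Conventions the definition leaves open are resolved as
follows and recorded in output metadata:

* A larva whose first trial is invalid or has NTA exactly 0 is
  unclassified and excluded from the MI.
* Follow-up trials that are invalid *or have an exactly zero statistic*
  are dropped from numerator and denominator. A zero is uninformative
  about direction; counting it as a mismatch would pull the null
  expectation below 0.5 and break the Binomial(k, 1/2) permutation null.
  (Exact zeros are measure-zero for real NTA data but common for the
  discrete net turn counts of synthetic or kinematic data.)
* At least 2 informative follow-ups (configurable) are required; otherwise
  the MI is missing.

For kinematic data, each trial is summarized by the **percent of routine
turns executed rightward**, a larva by the unweighted mean over its four
trials, with larvae excluded unless every trial has at least three routine
turns. Bias is decomposed as *magnitude* `|%R − 50|` and *direction*
`sign(%R − 50)`; 33/66% cutoffs give the categorical L/R classes used for
multiday grouping, and `select_consistent_larvae()` applies the
breeder-selection filter (outer quartile of mean %R *and* all four trials
in the same direction, with inclusive linear-interpolation quartiles).

## The Markov-chain null model

The null simulator reproduces the *structure* of an observed cohort — the
same larvae with the same per-trial turn counts — while destroying
individual bias:

* the first turn of each trial is a fair coin;
* each subsequent turn repeats the previous direction with probability
  `p_same`.

`p_same` comes from the empirically measured **lock index** `L` through the
linear map `p_same = (100 + L) / 200` (`lock_to_prob()`), giving 0.814 for
the light-off condition (`L = 62.8`) and 0.566 under baseline illumination
(`L = 13.2`).

`mc_bias_test()` pools the simulated per-larva mean %R values, takes the
`tail/2` and `1 − tail/2` quantiles as thresholds (so ~10% of simulated
larvae fall outside by construction, with default `tail = 0.10`), counts
observed larvae strictly outside the thresholds, and reports
`p = (# simulations with at least as many extreme larvae) / n_sims`.
When no simulation reaches the observed count the p-value is reported as
a bound below `1 / n_sims` with `p_is_bound` set; the `(k+1)/(n+1)`
convention is available as an option. Thresholds are always derived from
the simulation at run time, never hard-coded, since printed threshold
values in any one experiment are themselves simulation output.

`permutation_match_test()` compares the cohort mean MI against 0.5: each
larva's null MI is `Binomial(k_i, 1/2) / k_i` with its *own* number of
informative follow-ups `k_i`, so exclusion-depleted larvae are handled
faithfully. The default is two-sided on `|mean − 0.5|` because deviation,
not direction, is the hypothesis; one-sided options exist.

### Numerical behaviour and operating characteristics

The simulation core is vectorized over all trials of all simulated cohorts
(cost scales with total turns), and discrete outcomes are compared with
exhaustive chain enumeration in the test suite (total-variation distance
below 0.01 at 10^5 draws for small trials). One operating characteristic
deserves note: the exceedance count of an 89-larva cohort is a small
integer, so the Monte-Carlo p-value is discrete and the test is *slightly
conservative* near conventional levels — the probability of `p ≤ 0.05`
under the null sits just below 0.05 by roughly the probability mass of the
critical count (a few hundredths). The calibration helpers
(`calibrate_mc_bias()`, `calibrate_match_permutation()`) measure this
directly; the permutation test's null p-values are approximately uniform.

## The synthetic-data generators

The generators define the study conditions under which everything is
tested; their defaults are fixed once:

| Parameter | Default | Rationale |
|---|---|---|
| trials per larva | 4 | four light-off trials per assay |
| turn counts | Poisson(8), truncated at 3 | matches the ≥3-turns analysis filter; the true per-trial count distribution is not published, so the mean is a placeholder varied in sensitivity tests |
| `lock_prob` | 0.814 | light-off lock index 62.8 |
| `bias_strength` π | 0.7 | larvae initiate movement in their preferred direction on ~70% of trials |
| trial window | 10 s | kinematic recording duration |

Bias is injected *only on each trial's first turn* (preferred direction
with probability π), with persistence `p_same` thereafter — the minimal
extension of the null simulator, which it reproduces exactly at π = 0.5.
A consequence worth knowing: first-turn bias dilutes through the chain, so
even π near 1 yields only ~65% preferred-side turns per larva; planted
effects are moderate by design, and tests of monotonicity across π use
large cohorts to resolve the ordering.

One master seed drives per-larva (and per-neuron) substreams derived with
a fixed integer mix, so enlarging a cohort never reshuffles previously
generated animals.

The calcium generator emits raw traces `F_base + F_base·kernel + noise`
sampled at 0.96 Hz with a light/dark/light epoch plan (60 s each). The
relight epoch deviates from a minimal light+dark plan deliberately:
neurons responding to the restoration of illumination can only exist if a
dark-to-light transition is recorded. Planted responder fractions default
to 15.3% OFF and 4.7% ON, the observed cohort composition. The kernel is
a linear 2-frame rise to 1.0 ΔF/F with exponential decay (τ = 28 s),
placing the time to half-maximal activity near 21.5 s — the scale the
assay reports. Two-epoch plans remain fully supported.

What the generators do **not** emulate: arena geometry and kinematics
(turns are abstract signed events), slow drift or bleaching in
fluorescence, correlated noise across neurons, motion artifacts, and
inter-trial variability in responder strength. Passing recovery tests
therefore demonstrates correctness of the *analysis chain*, not robustness
to every artifact of real recordings.

## Calcium responder classification

`compute_dff()` normalizes `(F_t − F0)/F0` with `F0` the mean intensity of
the first baseline (light) epoch of the trial-averaged trace, and `S` the
baseline standard deviation of ΔF/F. Classification follows the
3S/3-frame rule: a neuron is a responder when ΔF/F exceeds `3S` on at
least three successive frames; the earliest qualifying run's first frame
is the onset. Class is assigned by onset epoch — dark onsets are
light-OFF responders, onsets in a light epoch that follows a dark epoch
are light-ON responders, and anything else (including excursions confined
to the baseline) stays unclassified. Decisions the rule leaves open:

* **Trial handling.** Classification runs on the across-trial mean trace
  by default; `average_trials = FALSE` classifies each trial separately,
  and both modes are labelled in the output.
* **Degenerate baseline.** If `S = 0` (constant baseline), any positive
  excursion of sufficient length qualifies; the call is flagged
  `zero_baseline_sd`.
* **Timing.** Time to half-max runs from the stimulus (the transition
  starting the onset epoch) to the first post-peak half-maximal crossing,
  with linear interpolation between the ~1 Hz frames; traces that never
  return are flagged rather than assigned a time.
* **Rounding.** Summaries report unrounded percentages together with raw
  counts, so either rounding or truncation conventions (15.4 vs 15.3 for
  46/299) can be recomputed.

## Effect sizes

Cohen's *d* uses the pooled n−1 standard deviation by default (the
control-group alternative is an option, since the convention used for the
reported values is not stated); the rank-biserial *r* is the midrank-based
dominance statistic `(#{x>y} − #{x<y})/(n_x n_y)`, verified in the test
suite against brute-force pair counting and the Mann–Whitney U statistic;
partial η² is `SS_effect / (SS_effect + SS_error)` with the sums of
squares supplied by whatever ANOVA routine ran the test. The group tests
themselves (t, Mann–Whitney, ANOVA) are delegated to standard routines.

## Problem sizes used in the shipped checks

The test suite and acceptance script run at desk scale, chosen to finish
in minutes on one CPU while leaving Monte-Carlo noise well below the
tolerances checked: 10,000 simulated cohorts of 89 larvae for the null
tail property; 1,000 null cohorts at 1,000 simulations each for type-I
calibration; 400 runs at 2,000 permutations for p-value uniformity; 2,000
larvae per bias level for the monotonicity check; 300-neuron cohorts for
responder recovery.

## Known limitations

* The Monte-Carlo machinery targets cohorts up to a few hundred larvae
  and 10^4–10^5 simulations; everything is held in memory.
* The lock index is treated as a known constant, as in the original
  procedure; uncertainty in its estimation is not propagated.
* The responder rule tests only positive excursions; suppressed
  (negative-going) responses are not classified.
* No multiple-cohort corrections are applied — tests are per-experiment.
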