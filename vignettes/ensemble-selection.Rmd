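---
title: "Selecting multimodal late-fusion ensembles by recall and diversity"
author: "EnsembleFuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting multimodal late-fusion ensembles by recall and diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The selection problem

Late fusion combines the *label* outputs of modality-specific classifiers
by majority vote: tabular learners on clinical variables emit one label
per patient, CT networks one label per slice (reduced to a patient label
by a per-patient majority over slices). Given a pool of `M = M_Cl + M_Im`
trained unimodal models, the package selects the subset to fuse. Two
forces matter. An ensemble should be *sensitive*: in a prognosis setting
the positive class is short survival, and a missed positive patient is a
patient excluded from treatment intensification, so recall on that class
is the performance score. And its members should be *complementary*: a
majority vote only repairs a member's mistake when the other members do
not make the same mistake.

### Scores

For one validation split, recall is `R = TP / P` on the patient-level
majority-vote labels. Diversity of a member pair is one minus the
inter-rater kappa of their joint correct/incorrect contingency
`(N11, N10, N01, N00)`:

```
K = 1 - 2 (N11 N00 - N01 N10) /
        [ (N11 + N10)(N01 + N00) + (N11 + N01)(N10 + N00) ]
```

`K` is 0 when the two models always agree (kappa 1), about 1 when their
errors are independent (kappa 0), and 2 in the limit of exactly
complementary models (kappa -1). Ensemble diversity `K(E)` is the mean of
`K` over all unordered member pairs. Both scores are averaged across the
validation splits of every bootstrap fold, giving `r_bar` and `k_bar`.

A point worth stating explicitly: `K` genuinely ranges over `[0, 2]`, not
`[0, 1]` — any pair with negative kappa (worse-than-chance agreement)
yields `K > 1`. The implementation follows the formula and does not clip.
One can show `0 <= K <= 2` always holds, because
`2|N11·N00 − N01·N10|` never exceeds the denominator; the test suite
verifies this over tens of thousands of random contingencies. When the
denominator vanishes the formula is undefined and the implementation
returns the continuity limits: 0 for identical prediction vectors, 2 for
exactly opposite ones.

### Objective and constraints

```
E* = argmin_E (1 - r_bar(E))^2 + (1 - k_bar(E))^2
s.t. |E| > 1,  |E| odd,  |E|_Cl >= 1,  |E|_Im >= 1
```

The odd-size constraint makes across-model majority votes tie-free; the
modality floors force true multimodality. The search is exhaustive over
all feasible subsets up to `maxSize`. Since `k_bar` may exceed 1, the
squared diversity term also penalises *over*-diverse (anti-correlated)
ensembles — a deliberate consequence of the squared form.

`maxSize` defaults to 3. With pools of tens of models, unbounded
exhaustion is combinatorially explosive (`2^M` subsets), while selected
late-fusion ensembles in practice are small; the cap is exposed so small
pools can be searched completely. The feasible-set cardinality equals
`sum over odd s in [3, maxSize] of C(M, s) - C(M_Cl, s) - C(M_Im, s)`,
which the tests verify against enumeration.

### Pareto front and dominance

Minimising the squared distance to the ideal point `(1, 1)` is a
scalarisation of the two-objective problem, and `E*` should sit on the
Pareto front. Because `k_bar` can exceed 1, dominance is defined on the
component distances `|1 - r_bar|` and `|1 - k_bar|` rather than on raw
maximisation of `(r_bar, k_bar)`: candidate A dominates B when A is at
least as close to the ideal in both components and strictly closer in
one. For `k_bar <= 1` the two definitions coincide; defining dominance
through the ideal point keeps the invariant "the argmin is never
dominated" true in general, which raw maximisation would violate for
candidates straddling `k_bar = 1`.

### Tie-breaking

Equal objective values are resolved deterministically: smaller ensembles
first, then the lexicographically smallest sorted member tuple. Scores
are rounded to 10 significant digits before ranking so that
mathematically equal scores reached through different floating-point
paths (e.g. diversities symmetric about 1, which give identical squared
terms) still fall to the documented tie-break rather than to the last
bit of rounding noise. Exact ties do occur in practice — two models with
identical predictions induce candidate ensembles with identical scores.

## Baseline ensembles

The report places `E*` against the constructions a practitioner would
otherwise use: `E_R` and `E_K` (maximise `r_bar` or `k_bar` alone, same
constraints and tie-break); the mean ± sd over *all* feasible candidates;
`E_post3`, the trio of the three unimodal models with the largest mean
*test* recall (an a-posteriori construction that peeks at the test sets);
the average over all candidates containing the two per-modality
a-posteriori recall leaders; and the relaxed optimum with the modality
floors dropped (only the odd-size constraint kept). The validation-based
baselines (`E_R`, `E_K`, relaxed) are computed inside `selectOptimal()`;
the test-based ones need test predictions and are assembled by
`buildReport()`.

## Evaluation protocol

Evaluation uses repeated random patient-grouped splitting: `nReps`
(default 5) independent partitions into train/validation/test at
80/10/10. Proportions this strict are incompatible with with-replacement
resampling, so "bootstrap" here is Monte-Carlo cross-validation without
replacement. Splits are stratified by prognosis class by default — the
cohorts this targets are near-balanced by construction (median-split
labels) — and all slices of a patient follow the patient, so no patient
leaks across splits. Split sizes are rounded by cumulative flooring
within each stratum (`diff(floor(cumsum(n_k * fractions)))`): the train
split gets exactly `floor(0.8 n_k)`, and the rounding remainders fall to
validation/test in turn, keeping every split within one patient of its
exact proportion per stratum. Metrics are reported as across-fold mean ±
sample sd, in percent, two decimals, rounded half away from zero. With a
single fold the sd is 0 by convention.

The positive class is label 1, the short-survival class; "F-score" is F1
on that class. A test split with no positive patients makes recall
undefined and is reported as an error rather than silently skipped; the
fully degenerate F-score case (no positives, no positive predictions) is
defined as 0 with a warning.

## Clinical preprocessing

The seven-descriptor schema (age, CTV volume, sex, histology, stage,
T stage, N stage) is fixed; the category lists are configurable. Missing
numeric values take the training-split median (even counts: mean of the
two central values), missing categoricals the training-split mode (ties:
lexicographically smallest), except histology, where a missing value is a
meaningful state — no histopathological examination — and becomes the
literal category `unknown`. One-hot encoding expands each categorical
feature to one indicator per declared category; the default schema yields
2 numeric + 19 indicator columns. Published descriptions of comparable
pipelines cite richer encodings (27 columns) via tumour sub-stage letters
that are not enumerated in the corresponding cohort tables, which is why
the schema is configurable rather than hardcoded. Min–max normalisation
scales the numeric columns with training-split bounds; out-of-range
validation/test values are clipped to `[0, 1]`, preserving the stated
range guarantee.

## Synthetic data: what it emulates, and what it does not

`simulateCohort()` draws patients independently from per-feature
marginals (defaults matching a published 191-patient locally-advanced
NSCLC cohort: 69.6% male, adenocarcinoma-dominated histology with a
13.6% `unknown` share, 83.8% stage III, median OS 15.64 months), injects
missing values at the stated rates, and assigns the binary class by the
median split of a log-normal survival time — hence near-balanced labels.
Feature-feature and feature-outcome correlations are *not* modelled: the
cohort generator validates summarisation and preprocessing, not
classifier training.

`simulatePredictions()` emits classifier outputs directly, bypassing
model fitting. Each patient carries a latent difficulty `d ~ N(0, 1)`;
model `m` is correct on a sample with probability
`plogis(a_m - w_m * d)`, with `a_m` calibrated by root-finding so the
realised marginal accuracy matches the spec's target. The difficulty
weight `w_m` controls graded error correlation between models (checked to
be monotone in the tests); a shared `flip_group` reuses one uniform error
draw per sample, the maximal-redundancy limit: equal-accuracy group
members predict identically (pairwise `K = 0`) and a lower-accuracy
member errs on a superset of its partner's mistakes. Slice-granularity
models emit per-slice labels with independent per-slice noise around the
patient's difficulty; slice counts are drawn uniformly from a
configurable range (default 3–7), shared across models. What passing
tests on these pools show is that the *selection machinery* optimises
what it claims to optimise; they cannot show that real CNN/tabular pools
satisfy the generator's assumptions (class-symmetric errors, exchangeable
patients, fold-independent error draws).

### The planted-optimum scenario

`plantedOptimumScenario()` builds a pool whose best trio is known by
construction: an accurate clinical model `cl1` (patient-level accuracy
0.70) and two accurate, mutually decorrelated imaging models `im1`, `im2`
(slice accuracy 0.62, about 0.70 at patient level after slice majority) —
strengths inside the band real unimodal prognosis models occupy (roughly
0.50–0.75) — against decoys that are redundant by construction: `im3` and
`im4` duplicate `im1` and `im2` exactly, and `cl2` is a chance-level
degraded copy of `cl1` (0.50, errors a superset of `cl1`'s). Any trio
pairing a model with its copy collapses in diversity; any trio swapping
in `cl2` loses recall pathwise; duplicate-for-twin swaps tie exactly and
fall to the deterministic tie-break.

The scenario uses 40/40/20 splits rather than the production 80/10/10,
for statistical power: selection scores are estimated on validation
patients, and with ten of them the sampling noise of the kappa estimate
(sd about `1/sqrt(n)`) and of vote recall would swamp the planted
margins regardless of implementation; ten test patients would likewise
quantise per-fold recall in 20-point steps, too coarse to compare
selection strategies. The train share is inert because the generator
emits predictions rather than fitting models. At this design, the
acceptance suite observes the planted trio recovered in 96–100% of
50-seed batches and the multiobjective optimum matching or exceeding the
recall-only baseline's mean test recall.

## Numerical and degenerate-input conventions

* Kappa with a vanishing denominator: continuity limits (0 identical,
  2 opposite).
* Slice-level ties (even slice counts) resolve by a configurable policy,
  default positive — favouring sensitivity, consistent with the
  recall-driven objective. Across-model votes never tie (odd sizes).
* Whether a model is slice- or patient-granularity is inferred from its
  records (patient-level records have `sample_id == patient_id`), so
  aggregation is uniform across the pool.
* Accuracy calibration at target 0 or 1 with positive difficulty weight
  is unreachable through the logistic link; the generator warns and emits
  exact deterministic labels.
* File formats: CSV with header (plus a patient-truth sidecar) and an
  equivalent single-document JSON form; both lossless, both validated
  row-by-row on load with errors naming the offending rows.
* CLI runs write their resolved configuration (tool version and
  parameters, no timestamp) next to their outputs, keeping repeated runs
  with one seed byte-identical; timestamps go to the stderr log.

## Problem sizes used by the test suite

Unit tests run on pools of up to 8 models, 50–100 patients and 2–5
folds. The acceptance checks use: the 191-patient published cohort counts
(exact percentage reproduction); 200 random instances of up to 3 clinical
+ 5 imaging models, 50 patients, 2 folds (brute-force equivalence of all
three selection modes); 10,000 random contingencies (kappa properties);
and 50 planted scenarios of 100 patients and 5 folds (recovery and
baseline comparison). These sizes exercise every code path while keeping
the whole suite inside a few minutes on one CPU.

## Known limitations

* The exhaustive search is exponential in `maxSize`; the default cap of 3
  reflects the intended regime. No heuristic search is provided, by
  design.
* Label-level fusion only: probabilities, logits and weighted votes are
  out of scope.
* The recall-driven objective has no guard against classifiers biased
  toward the positive class (an always-positive model has perfect
  recall); the generator's error model is class-symmetric, so this
  failure mode is not exercised here.
* The synthetic cohort generator models marginals, not dependence; it
  cannot stand in for real multimodal data when assessing clinical
  validity.
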