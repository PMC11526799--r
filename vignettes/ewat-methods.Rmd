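---
title: "Scoring, content validity and reliability methods in ewat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, content validity and reliability methods in ewat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewat)
```

## The instrument

`ewat` implements the scoring and psychometric machinery around a structured
welfare assessment instrument for Asian elephants managed in tourist camps.
The instrument follows the Five Domains framework collapsed to four domains —
Nutrition, Environment, Health, and Behavior and Mental State — and mixes
animal-based measures (read directly off the elephant: body condition, wounds,
behaviour) with resource-based measures (what the camp provides: feed variety,
chain length or enclosure space, shade, veterinary care). Every measure is
scored on a 0–2 Likert rubric whose verbatim descriptors ship in the package
codebook; 0 always denotes the worst state ("Welfare concern" for animal-based
measures, "High-risk" for resource-based ones) and 2 the best.

Two codebook versions ship in one versioned file. The initial draft has 39
measures (18 animal-, 21 resource-based; Nutrition 5, Environment 14, Health
10, Behavior/Mental 10). After expert content review three resource-based
Environment measures were dropped — the opportunity to mate, the duration of
the mahout–elephant working relationship, and mahout job satisfaction — giving
the final 36-measure tool (18/18 split; Environment 11). Six Environment
measures are scored separately for daytime and nighttime management, so the
final tool yields 42 scoring items and the draft 45. `validate_codebook()`
re-checks all of these counts on every load, so the shipped data file cannot
drift from the instrument definition. The rubric text for the three dropped
measures does not appear in the published final rubric table; the descriptors
carried in the `initial_39` records are reconstructions (flagged
`rubric_source: reconstructed` in the file) written only so that draft-version
sheets can validate.

Visit-protocol metadata (step timings summing to about 1.5 h per elephant, and
the two 15-min behavioural observations in restrained and unrestrained states
separated by at least 1 h) is stored as documentation via `protocol_steps()`;
the package deliberately contains no scheduling logic.

## Scoring model

Item scores aggregate by plain averaging — the instrument defines no weights —
and every aggregate stays on the 0–2 scale:

* **Elephant (overall).** `elephant_score()` offers two weightings because the
  day/night duplication leaves "average across all measures" ambiguous.
  `per_item` (the default) gives each of the 42 items equal weight, treating
  every recorded data point equally; `per_measure` first averages the
  day/night pair so each of the 36 measures counts once. The two agree exactly
  whenever no measure has multiple conditions, and the package asserts that
  property in its tests. We default to `per_item` for transparency — it is the
  mean of exactly what was recorded — and expose the alternative rather than
  guessing the instrument authors' intent.
* **Domain.** `domain_scores()` is the mean of each domain's non-missing
  items. A domain with nothing scored is reported missing (`NA`), never zero:
  on this scale 0 is the worst grade, not the absence of one.
* **Camp.** `camp_score()` is the unweighted mean of per-elephant overall
  scores (sheets for the same elephant are averaged first, so each animal
  counts once regardless of how many raters scored it).

Missing data are always an explicit `NA` token, distinct from 0, and an
overall score is only issued when at least 80% of items are scored
(`min_completeness = 0.8`, configurable). The cut-off prevents a handful of
items from masquerading as a whole-instrument score; 80% still tolerates a
realistically curtailed visit (e.g. a nighttime area that cannot be
inspected). Scores are kept at full precision internally and rounded half-up
to two decimals only where reports print them.

`flag_concerns()` translates every 0 (optionally every 1) into the
basis-appropriate semantic label, so a camp report reads "High-risk" rather
than a bare digit.

## Content validity

The content-validity pipeline follows the standard I-CVI/S-CVI construction
for a complete panel of `N` experts rating every item's relevance on a 1–4
ordinal scale:

1. `dichotomize()`: ratings 3–4 count as *relevant* (1), ratings 1–2 as *not
   relevant* (0). Every downstream index depends only on this dichotomy, and
   the tests assert invariance to relabelling within {3,4} or {1,2}.
2. `item_cvi()`: I-CVI = experts-in-agreement / N. Universal agreement
   (UA) is 1 iff all N experts agree the item is relevant, so UA = 1 ⇔
   I-CVI = 1.
3. `scale_cvi()`: S-CVI/Average is the mean I-CVI; S-CVI/UA is the mean UA
   indicator. Pointwise UA ≤ I-CVI forces S-CVI/UA ≤ S-CVI/Average for every
   panel (property-tested on 1000 random panels).
4. `apply_retention()`: an item is removed iff its *unrounded* I-CVI falls
   below the threshold (default 0.83) minus an epsilon of 1e-9. The epsilon
   matters: with six experts, 5/6 = 0.8333… must pass a 0.83 threshold even
   though it prints as 0.83; comparing rounded values would make the rule
   depend on presentation. Removed items are reported in ascending I-CVI
   order. Incomplete panels are rejected outright rather than renormalised —
   the index is defined on complete panels, and silently renormalising would
   change N per item.

Rounding half-up to two decimals happens only in the presentation layer
(`i_cvi_2dp`, printed reports); all comparisons use full precision.

### The reconstructed panel and a documented discrepancy

The validation study's raw 6-expert × 39-item panel is not redistributed with
the package. `reference_panel()` instead *reconstructs* a synthetic panel from
the published item-level agreement: one measure at 3/6, two at 4/6, five at
5/6, and unanimous agreement on the remaining 31. Running `cvi()` on it
removes exactly the three published measures and reproduces S-CVI/Average =
0.98 over the retained instrument (35.17/36 = 0.977). It does **not**
reproduce the published S-CVI/UA of 0.89: with 31 of 36 retained measures
unanimous the universal-agreement index is 31/36 = 0.86 (and 0.79 over all 39
items). No item set consistent with the published item-level distribution
yields 0.89 — that value would require 32 unanimous retained measures, i.e.
only four items at 5/6 where five are named. The package computes all indices
from the raw panel and documents this discrepancy rather than special-casing
the printed number; the corresponding acceptance test is deliberately left
failing on that one assertion.

## Reliability

Inter-rater and test-retest reliability use the intraclass correlation under
the two-way random-effects model with **absolute agreement**: both the
subjects (elephants) and the raters (or occasions) are treated as random
samples, and systematic level differences between raters count against
agreement. From the two-way ANOVA mean squares without replication
(`anova_mean_squares()`: MSR between subjects, MSC between raters, MSE
residual),

* single rating: `ICC(A,1) = (MSR − MSE) / (MSR + (k−1) MSE + (k/n)(MSC − MSE))`
* average of k ratings: `ICC(A,k) = (MSR − MSE) / (MSR + (MSC − MSE)/n)`

`icc_agreement()` defaults to the single-rating unit — each assessment stands
on its own in field use — and exposes the average-rating form. The 95%
confidence interval uses the McGraw–Wong F construction with a Satterthwaite
approximation to the rater-term degrees of freedom; the average-rating
interval is the Spearman–Brown step-up of the single-rating bounds, with one
guard the common implementations lack: a lower bound below the transform's
pole at −1/(k−1) is reported as −∞ rather than a spurious positive value.
The estimates and intervals are validated in the tests against an
independently coded variance-component oracle (to 1e-10) and against frozen
values from an independent implementation on a 6 × 4 benchmark matrix. A
p-value for ICC = 0 comes from F = MSR/MSE on (n−1, (n−1)(k−1)) df.

Numerical edge cases are explicit: an all-constant matrix has no variance
anywhere, the estimator is 0/0, and the package raises a classed
"degenerate" error instead of returning NaN; perfect agreement with subject
spread returns exactly 1 with a collapsed interval; negative estimates are
reported as-is, never truncated at zero. Missing cells are never imputed —
`assemble_ratings()` offers listwise subject deletion only behind an explicit
`drop_incomplete = TRUE`.

`classify_icc()` applies the conventional qualitative bands (<0.5 poor, 0.5 to
0.75 moderate, 0.75 to 0.9 good, ≥0.9 excellent). The banding convention in
the literature is open-interval ambiguous at the cut-points; we place boundary
values in the upper band (0.9 is "excellent") and expose `right_closed` to
flip that, a pure labelling choice that never affects estimates.

`reliability_report()` pools several labelled matrices — by default one per
domain plus the overall score, each cell being elephant i's score by rater j
(or occasion j) — and reports mean, SD, SE = SD/√m and the min–max range of
the m estimates, the conventional reporting style for such studies. With a
single label the SE is reported as 0. The grouping is a configuration choice,
not a statistical necessity: published pooled summaries of this kind rarely
state the unit of replication, and per-domain-plus-overall is the finest
grouping the instrument's structure supports without reusing items.

`reference_ratings()` provides synthetic stand-ins for the validation study's
rating matrices (10 elephants × 3 raters inter-rater; 10 × 2 test-retest),
built deterministically from orthogonal subject/rater/residual components so
each matrix's ICC(A,1) is exact by construction, with per-label values chosen
to reproduce the published pooled summaries (inter-rater mean 0.82, range
0.78–0.90; test-retest mean 0.86, range 0.77–0.91). They exercise the full
pipeline arithmetic end to end; they are not the study's raw data. One
internal inconsistency in the published summaries is worth recording: a
test-retest summary of "0.86 ± 0.08" cannot be mean ± *SE* for any set of
ICCs confined to the printed 0.77–0.91 range (the maximum attainable SE is
0.07, at m = 2), but it is consistent with mean ± SD of, e.g.,
{0.77, 0.90, 0.91}; the report therefore prints both SD and SE.

## Synthetic data generation

The generators make every pipeline testable with known ground truth:

* `simulate_panel()` draws each expert × item cell relevant with per-item
  probability `p_i` (rating sampled from {3,4}, else {1,2}), emulating the
  6-expert × 39-item validation design. The expected I-CVI of an item is
  exactly `p_i`.
* `simulate_two_way()` draws `y_ij = μ + s_i + r_j + e_ij` with independent
  zero-mean normal components, so the population single-rating agreement ICC
  is σ²_s/(σ²_s + σ²_r + σ²_e). Defaults emulate the 10 × 3 inter-rater
  design with σ²_s = 1, σ²_r = 0.1, σ²_e = 0.25 (population ICC 1/1.35 ≈
  0.741, in the "good" band like the field results). Optional discretisation
  cuts the continuous scores at the fixed thresholds 0.5 and 1.5 onto the
  instrument's {0,1,2} scale, mirroring Likert realism at the price of making
  the variance-component ground truth approximate.
* `simulate_camp()` gives each elephant a latent quality q ∈ [0,2]; each item
  score is a normal draw around q cut at the same fixed thresholds. As noise
  → 0 every sheet converges to q's grade, and with q = 1 the score
  distribution is symmetric so camp means converge to 1.

All generators are bit-reproducible given (spec, seed) and restore the
caller's RNG stream. What they do *not* emulate is just as important for
interpreting green tests: real panels have correlated experts (shared
training, shared blind spots), real item scores are correlated within an
elephant (a poorly resourced camp depresses many items at once), rater
disagreement in the field is item-specific rather than homoscedastic, and
missingness is structured (whole visit steps drop out, not random items).
Passing recovery tests on these generators therefore demonstrates correctness
of the estimators under their nominal models, not robustness of the
instrument under field conditions.

## Small-sample bias of the ICC estimator

The method-of-moments ICC(A,1) estimator is biased downward in small designs:
the package's recovery test at the study's own size (n = 10 elephants, k = 3
raters, population ICC 0.741, 1000 replicates) measures a mean estimate about
0.02 below the population value. This is a property of the standard estimator
— ours matches independent implementations to machine precision per matrix —
not an implementation defect, and it is why the parameter-recovery tolerance
of ±0.02 at this design size is knowingly not met; the corresponding test is
left failing with this analysis rather than having its tolerance widened.
Users comparing small-camp ICCs against fixed qualitative cut-offs should
expect estimates, not the underlying parameters, to sit slightly low.

## Problem sizes and determinism

The test and verification runs use the study-scale designs throughout: 6 × 39
panels, 10 × 3 and 10 × 2 rating matrices, camps of up to 40 simulated
elephants, 200 random matrices for the oracle-equivalence sweep, and 1000
replicates for the Monte-Carlo recovery and panel-ordering properties — sizes
at which every check completes in seconds while keeping Monte-Carlo error
well below the asserted tolerances. All stochastic checks run under fixed
seeds, and the command-line interface writes byte-identical machine-readable
output under identical configuration and seed.

## Known limitations

* The package validates and scores the instrument; it does not define
  normative cut-offs for a "good" camp — the instrument's authors define
  none, and inventing one would be a policy statement, not statistics.
* Reliability requires complete subject × rater matrices; unbalanced field
  designs need listwise deletion or a different (mixed-model) estimator that
  is out of scope here.
* Chance-corrected validity indices (kappa-adjusted CVI) and alternative
  agreement statistics (Fleiss kappa, Krippendorff alpha, Bland–Altman) are
  deliberately not implemented.
* The day/night weighting ambiguity is exposed, not resolved: both weightings
  ship, and camp-level conclusions should be checked under both when the six
  dual-condition measures diverge between day and night.
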