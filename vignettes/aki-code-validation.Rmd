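---
title: "Validating ICD-10 AKI codes against creatinine-based AKIN staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating ICD-10 AKI codes against creatinine-based AKIN staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Discharge abstracts code diagnoses, not laboratory values. When researchers
identify acute kidney injury (AKI) in administrative data through the ICD-10
N17x family, every downstream estimate inherits the code's errors. The
definitive way to quantify those errors is a linked validation study: take a
cohort whose serum creatinine history is known, compute a creatinine-based
reference standard, and cross-tabulate it against the code. `akicode`
implements that design end to end for kidney transplant recipients — a
population with high AKI risk and dense creatinine surveillance — together
with a synthetic-data generator that stands in for the linked patient-level
data, which privacy rules place permanently out of reach.

This vignette records the package's modelling decisions, parameter defaults
and known limitations; the README shows the basic workflow.

## Reference standard: creatinine-only AKIN staging

`akin_stage(baseline, peak)` implements the adapted AKIN criteria using
serum creatinine alone. With ratio $r = \mathrm{peak}/\mathrm{baseline}$ and
rise $d = \mathrm{peak}-\mathrm{baseline}$ (μmol/L): stage 3 when $r > 3$ or
(peak $> 354$ and $d \ge 44$); else stage 2 when $r > 2$; else stage 1 when
$d \ge 26.4$ or $r \ge 1.5$; else stage 0.

Decisions that the criteria's prose leaves open, fixed here and exercised by
tests:

* "$x$-fold increase" means the ratio reaches $x$ (an increase *to* $x$
  times baseline, the standard staging reading), not baseline plus $x$
  times baseline.
* Boundaries: $r = 2$ exactly is stage 1, $r = 3$ exactly is stage 2, a
  peak of exactly 354 μmol/L fails the strict "> 354" clause, and $d = 44$
  exactly meets "at least 44".
* The urine-output criterion and the 48-hour timing window of the full
  AKIN definition are deliberately omitted: neither is observable in
  admission-level administrative data, and clinical practice rarely applies
  the strict timeline. The stage-3 absolute clause reads $d$ as the acute
  increase, since no finer time structure exists in the data model.
* The dialysis-initiation route to stage 3 is out of scope (no dialysis
  data are modelled).

**Baseline selection** (`select_baseline`): the most recent creatinine
drawn 14–183 days before admission, both bounds inclusive ("2 weeks" = 14
days, "6 months" = 183 days; the source criteria give no day counts, so
these are configuration with documented defaults). Draws under 14 days
before admission are excluded as possibly already part of the episode.
Same-day duplicates on the chosen date are averaged — an arbitrary but
stated tie rule. **Peak selection** (`peak_creatinine`): maximum in-stay
value, ties broken by earliest date.

A consequence of the staging geometry worth knowing: for baselines of
177 μmol/L or more, stage 2 is unattainable — any more-than-2-fold rise
from such a baseline exceeds 354 μmol/L with $d \ge 44$ and is promoted to
stage 3 by the absolute clause. `sample_peak_for_stage()` raises an
informative error for such requests, and the generator truncates baseline
draws below 170 μmol/L for planted stage-2 cases. Real stage-2 patients are
correspondingly concentrated at lower baselines; this is a property of the
staging rule, not of the implementation.

## Cohort eligibility

`filter_eligible()` applies five rules in a fixed cascade, counting each
exclusion against the first rule that fails so the flow diagram is
conservative (counts plus survivors equal input admissions): (a) first
kidney-only transplant (first graft, kidney organ); (b) admission at least
183 days post transplant, excluding post-operative AKI, delayed graft
function and early rejection; (c) at least one in-stay creatinine; (d)
admission inside the study window (default 2003-04-01 through 2012-12-31 —
the ICD-10 coding era and laboratory availability window of the original
setting, both configurable); (e) at least one baseline-window creatinine.
When several admissions survive, `select_index_admission()` draws one per
patient uniformly at random to avoid within-patient clustering; the draw is
seeded and reproducible. Comorbidity flags use a 3-year (1095-day) lookback
with user-supplied prefix lists, because the original code lists are not
part of this package.

## Coding algorithms

`code_positive()` matches the target family as a prefix on canonicalized
codes ("n17.0", "N17 0" and "N170" are equivalent), so N17 with any fourth
character counts and N18x (chronic kidney disease) never does. The three
algorithms read diagnosis types: any field; pre-admission type
(`PREADMIT`); most responsible (`M`, unique per abstract — duplicates are a
data-integrity error). The algorithms are evaluated independently by type,
and any-diagnosis positivity is by construction a superset of the other
two. Real discharge abstracts use richer type codes (M/1/2/W/X/Y...); the
mapping to `M`/`PREADMIT`/`OTHER` is an input convention.

## Accuracy statistics

`performance()` computes Sn, Sp, PPV and NPV with Wilson score intervals
($z = 1.959964$ at 95 %); zero denominators yield NA, never errors.
`positive_lr()` is Sn$/(1-$Sp$)$ with an undefined flag at Sp $= 1$.
Suppression (`apply_suppression`) marks a whole table when any cell is in
$[1, 6)$ — the usual "cells of 1–5" convention; the threshold is
configurable and zero cells never trigger. Suppressed rows render no
partial values.

### Rounding: how the published table was printed

Reproducing a printed table exactly requires knowing its rounding
convention. Plain half-up rounding to one decimal reproduces most but not
all of the published cells: six cells (one PPV point estimate and five
interval bounds) print 0.1 higher than one-step rounding of the exact
values, whose second decimals all fall in the .x45–.x49 band. Rounding
half-up to two decimals and then again to one — double rounding, a common
artifact of formatting already-rounded intermediates — reproduces every
cell. The package therefore exposes both conventions: `round_half_up()`
(one step) and `printed_percent()` (double), with the latter used by the
replica report and by the count-reconstruction oracle. The printed LR+
column is the one-step rounding of the ratio of the printed percentages;
computing LR+ from unrounded proportions instead changes four of the eight
rows by 0.1, and both modes are available (`lr_mode = "printed"` or
`"exact"`).

### Reconstructing latent counts

`reconstruct_counts()` inverts a printed row: given the cohort size,
reference-positive and code-positive margins, it enumerates every feasible
true-positive count, derives the other three cells, and keeps candidates
whose four statistics re-render to print. The inversion refuses to guess:
zero survivors is an inconsistency error, several survivors an ambiguity
error. For all eight unsuppressed published rows the survivor is unique.
The suppressed main-diagnosis/stage ≥ 1 row cannot be reconstructed from
print; `suppressed_row_completion()` supplies a synthetic completion
(tp 23, fp 2, fn 213, tn 286) that is consistent with every printed margin
and itself contains a small cell, so the replica reproduces the original
suppression. It is labelled synthetic wherever it appears.

## The synthetic-data generator

`generate_population()` emulates the statistical structure the analysis
assumes, not the clinical richness of real data. Defaults are the study
conditions of the validation setting:

| Parameter | Default | Basis |
|---|---|---|
| stage prevalences (0–3) | 0.55, 0.305, 0.04, 0.105 | observed stage mix (45 % any AKI) |
| baseline creatinine | lognormal, median 133, IQR 103–174 μmol/L | observed baseline distribution |
| coding profile | per-stage rates from the reconstructed counts (e.g. any-diagnosis: 8/288, 34/160, 10/21, 22/55 for stages 0–3) | implied by the latent tables |
| transplant→admission gap | lognormal, median 3.5 y, IQR 1.5–7.1 y, floor 183 d | observed time since transplant |
| baseline draw offset | lognormal, median 34 d, IQR 22–68 d, clipped to [14, 183] | observed draw timing |
| length of stay | uniform 2–14 d; peak drawn day 0–2 | plausible stays; observed peak timing |

Lognormal spread parameters are matched to the quoted IQRs via
$\sigma = \log(q_3/q_1) / (2 z_{0.75})$.

Design choices:

* **Round-trip guarantee.** Peaks are planted with
  `sample_peak_for_stage()`, which samples uniformly inside the requested
  stage's creatinine band while keeping a configurable margin (default
  1 μmol/L) away from boundaries, so staging recovers the drawn stage in
  100 % of cases — a tested invariant, not a tendency.
* **Joint code structure.** Only marginal per-stage coding rates are
  identifiable from a published table; the joint distribution across the
  three algorithms is not. The generator draws the any-diagnosis flag at
  its marginal rate and the admission/main flags conditionally inside it,
  which preserves all three marginals, guarantees the superset structure
  the classifier implies, and requires the admission/main profiles not to
  exceed the any-diagnosis profile (validated). This nesting is a modelling
  choice, flagged here.
* **Creatinine trajectories** are minimal: one baseline draw, the planted
  peak, one in-stay value strictly below the peak, and sometimes a draw a
  week before admission that is deliberately too recent to be a baseline
  (exercising the exclusion rule). The analysis consumes only baseline and
  peak, so richer trajectories would be untested decoration.
* **Multi-admission mode** spaces a patient's admissions at least 400 days
  apart so no stay's labs can fall inside another stay's baseline window.
* **Exact planting.** `plant_exact_dataset()` takes a full, mutually
  consistent set of 2×2 counts, derives stage sizes and per-stage code
  counts from the margins, assigns flags by prefix within each stage block
  (which nests the three algorithms' sets), and shuffles. Cell counts are
  then exact for any seed; only covariates vary. Inconsistent margins fail
  with errors naming the conflict.

What the generator does **not** emulate: comorbidity co-occurrence,
seasonal or secular admission trends, within-patient correlation of coding
behaviour across admissions, dialysis, post-discharge outcomes, and the
code-positive/negative creatinine-change medians of the original cohort
(planted deltas respect stage bands but are not calibrated to the published
contrast table). Passing tests therefore demonstrate correctness of the
pipeline's logic under the assumed structure, not fidelity to any real
population.

## Creatinine-change contrast

`change_summary()` reports median and IQR using linear interpolation
between order statistics (`stats::quantile` type 7; the original software's
convention is unknown and this choice is configurable in principle by
pre-rounding). `mann_whitney()` reports the midrank U (so
$U_x + U_y = n_x n_y$ exactly, ties included) with p-values from
`stats::wilcox.test`: exact enumeration for combined samples of 12 or fewer
without ties, otherwise the normal approximation with tie and continuity
corrections. Two-sided p-values are reported.

## Problem sizes used by the checks

The test suite verifies staging against a literal rule-table oracle on
10⁵ random pairs, monotonicity on a 100 × 100 grid, the generator
round-trip on 10⁴ pairs, Wilson intervals against a root-finding oracle on
10³ random (k, n), and parameter recovery over 200 replicates of
n = 50,000 (coverage of the Wilson intervals over the true Sn and Sp,
expected ≈ 95 %, asserted ≥ 93 %). These sizes were chosen to make binomial
noise negligible relative to the tested tolerances.

## Known limitations

* The eligibility windows (183/14 days, inclusive bounds) are documented
  conventions for prose like "6 months"; a study that used 180-day months
  or exclusive bounds would classify a handful of admissions differently.
* The reference standard inherits every limitation of creatinine-only
  staging: no urine output, no hydration-status conditioning, no timing
  constraint, and insensitivity to AKI that resolves before admission.
* Acute rejection has its own code family and plausibly absorbs some true
  AKI codings in transplant cohorts; the package neither models nor
  corrects for this.
* The suppressed-row completion is synthetic; analyses of the
  main-diagnosis algorithm against stage ≥ 1 on planted data reflect that
  choice, not published evidence.
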