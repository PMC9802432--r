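---
title: "Methods: CDST stratification and claims-based HRU analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CDST stratification and claims-based HRU analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdsthru)
```

## The problem

Vedolizumab is a gut-selective anti-α4β7-integrin antibody used in
moderate-to-severe Crohn's disease (CD). A points-based clinical decision
support tool (CDST) predicts the probability of response from five baseline
variables; stratifying patients by that probability should also stratify
their downstream healthcare resource utilization (HRU) — hospitalizations,
surgeries, emergency-department (ED) visits — and the associated costs.
This package implements the full claims-analysis pipeline: cohort
construction from longitudinal claims tables, CDST scoring, 12-month
outcome and cost extraction, and cross-stratum inference, plus a synthetic
claims generator so that every stage is testable without access to
proprietary claims databases.

## Scoring rules

The 5-variable score is

$$S_5 = 2\,[\text{no prior bowel surgery}] + 2\,[\text{no prior fistulizing
disease}] + 3\,[\text{no prior anti-TNF exposure}] + 0.4\,\text{albumin} +
\pi(\text{CRP})$$

with albumin in g/L (uncapped linear term) and the CRP penalty
$\pi(c) = 0$ for $c < 3$ mg/L, $-0.5$ for $3 \le c \le 10$, and $-3$ for
$c > 10$. Strata: high if $S_5 > 19$, intermediate if $13 < S_5 \le 19$,
low if $S_5 \le 13$. The 3-variable score keeps only the three clinical
terms (attainable values 0, 2, 3, 4, 5, 7); high if $S_3 > 3$, low
otherwise — equivalently, high iff at least two of the three favorable
factors are present, which the tests verify by exhaustive enumeration.

Two boundary conventions are pinned by unit tests:

* **CRP band edges.** "> 10" defines the heavy penalty, so CRP = 10.0
  takes −0.5; CRP = 3.0 is assigned to the middle band by plain reading.
* **Cut points.** Scores of exactly 19 and 13 fall in the intermediate and
  low strata respectively (the cut definitions are strict on the high
  side). Scores are compared with exact arithmetic; no rounding is applied
  to the albumin term.

Patients missing baseline albumin or CRP are excluded from 5-variable
analyses (and counted), never imputed: the tool is only defined on complete
laboratory input, and the 3-variable variant exists precisely for data
without labs.

## Cohort construction

The index date is the earliest claim for an index-drug code inside the
accrual window (default 2014-05-01 to 2018-03-31). Eligibility requires

1. age ≥ 18 at index (from birth year, so age is year-resolution);
2. two CD diagnosis claims before index, ≥ 30 days apart (inclusive: a
   30-day gap qualifies), the earlier on or after 2000-01-01;
3. one continuous enrollment span covering index − 183 days through
   index + 183 days ("6 months" is implemented as 183 days for unambiguous
   day arithmetic; both are configurable).

Overlapping or abutting enrollment spans are merged before the continuity
check; a configurable gap tolerance (default 0 days) decides what counts
as continuous. Attrition is logged per criterion in application order, each
patient counted against the first criterion failed.

Baseline features use three windows, all closed on the left and open on
the right except where a rule's wording forces otherwise: the three CDST
risk factors use the full pre-index history (anti-TNF exposure is lifetime,
matching its use as a cumulative treatment count); `prior_year_*` flags use
the 365 days before index; concomitant medications use the 365 days from
index. Baseline labs take the most recent result within a 90-day lookback
(the source analysis states no window; 90 days is a common claims
convention and is configurable); same-day duplicate results are averaged —
deterministic and symmetric, never an error.

## Outcomes and the ED reclassification rule

Within `[index, index + 365)` days:

* **hospitalization** — inpatient-setting claim with a CD diagnosis code;
* **surgery** — claim with a CD-surgery procedure code;
* **ED visit** — claim with an ED revenue code (0450–0459, 0981).

An ED visit that "results in" hospitalization or surgery must count as that
event. With line-item claims this needs an operational linkage window: an
ED claim is reclassified when a hospitalization or surgery claim occurs the
same day or the next day (configurable). When both occur, surgery wins —
it is the rarer, costlier terminal category. Claim lines whose dates are at
most one day apart are merged into a single episode so that multi-line
stays are not double counted. The conservation identity (ED claims before
reclassification = ED claims after + reclassified claims) is a tested
invariant.

## Costs

Paid amounts are converted to 2017 USD via a year→factor CPI table (the
published conversion factors are not printed, so the default table is the
identity; real factors are user-supplied configuration) and assigned to
exactly one of six categories with fixed precedence
(surgery > hospitalization > ED > endoscopy/scan > office visit > lab);
reclassified ED claims carry their cost into the linked category.
Annualization follows the printed rule: if the interval from index to the
end of continuous eligibility exceeds 12 months the actual expenditure is
kept, otherwise it is scaled by $365.25 / (\text{days} + 1)$. The
"> 12 months" boundary is tested as `days + 1 > 365.25`, consistent with
the formula's own denominator. Annualization is homogeneous of degree one,
so annualizing per category and summing equals annualizing the total; the
partition and homogeneity identities are tested.

## Statistical comparisons

Binary outcomes are compared across strata with Pearson's χ² without
continuity correction — the choice that exactly reproduces the published
p-values recomputed from printed counts (e.g. the two-cohort sex comparison
gives p = .729). Continuous costs use one-way ANOVA across three strata or
a two-sample *t*-test across two. The *t*-test pools variances by default
(consistent with the identity $t^2 = F$ for two groups, which is tested
numerically); a flag switches to the Welch form. Each continuous test has a
summary-statistics variant operating on (n, mean, SD) triplets; the
observation-level route computes the summaries and delegates to it, so the
two agree to machine precision by construction and are cross-checked
against `stats::aov()`/`stats::t.test()` in the tests. No multiplicity
adjustment is applied (the source analysis reports unadjusted p-values);
a warning flags expected cell counts below 5, where asymptotic χ²
p-values are unreliable.

## Verification against the published tables

The printed baseline counts, summary triplets and p-value columns ship as
plain-text CSVs; `verify_published()` recomputes every derivable value:

* percentages must round (half away from zero) to the printed 1-decimal
  value — all do;
* χ² p-values from integer counts must round to the printed precision (or
  fall below a printed "<" bound) — all 30 do;
* ANOVA/t p-values are recomputed from summaries that were themselves
  rounded to one decimal, so a check passes when the printed p is
  attainable somewhere in the ±0.05 rounding box of the means and SDs
  (evaluated at the box corners). For two-group checks the published
  variance assumption is unstated, so the pooled and Welch ranges are both
  accepted.

One check fails and is pinned as a known discrepancy: the three-stratum
total-cost ANOVA p-value recomputes to .0206 from its own printed means and
SDs, but is printed as .0170 — no configuration inside the rounding boxes
reaches it (the component categories' p-values all reproduce exactly). The
published tables also disagree internally about the low-stratum total cost
($32 931 in one place, $32 391.2 in the table); the tabulated value is
used, and the celebrated low/high cost ratio reproduces as 2.5 either way.

## The synthetic claims generator

`claims_sim_config()` fixes the study conditions. A latent response
stratum (high/intermediate/low, default mix 179 : 152 : 27 — the reference
cohort's split) drives everything a real cohort would correlate:

* risk-factor prevalences and prior-year event rates per stratum taken
  from the published baseline table (e.g. lifetime fistulizing disease
  8.4% / 38.8% / 77.8%; any prior anti-TNF 59.8% / 90.8% / 100%);
* baseline albumin N(42/37/31, 4) g/L and CRP band probabilities chosen so
  scored strata broadly track latent ones; 5% of patients have missing
  labs to exercise the 5-variable exclusion path;
* 12-month event probabilities matching the published outcome proportions
  where printed (hospitalization 19.0%/48.1% and surgery 8.4%/44.4% for
  high/low; intermediate values and ED rates interpolated plausibly);
* per-claim costs drawn log-normal per category (published cost SDs exceed
  means, indicating strong right skew; the distributional family itself is
  a modeling choice, not printed), with magnitudes giving mean annual
  totals near the published $13k–$32k range;
* enrollment: 400–1500 days pre-index and 365–1200 days post-index, with a
  configurable dropout probability (default 0.10) truncating post-index
  enrollment to 183–364 days to exercise annualization.

Each simulated patient is constructed eligible (index claim in window, two
qualifying diagnoses, covering enrollment), so cohort attrition is
exercised by dedicated fixtures rather than by the generator. Event days
are drawn in disjoint thirds of the follow-up window so a standalone ED
event never falls inside another event's linkage window; the
reclassification rule is exercised instead by a configurable fraction
(default 0.5) of hospitalization events that carry a same-day ED revenue
claim. The latent stratum is emitted in a separate truth table
(`truth.csv`) that `read_claims_dataset()` never loads.

What the generator does **not** emulate: real ICD-10/CPT vocabularies
(it uses a compact documented synthetic vocabulary plus the genuine
revenue/CPT ranges), payer adjudication, re-treatment episodes, seasonal
or secular trends, and correlation between event timing and cost size.
Passing recovery tests therefore demonstrates correctness of the pipeline's
arithmetic and logic under the planted model, not robustness to real-world
coding noise.

## Problem sizes and determinism

Identical `(config, seed)` reproduce byte-identical datasets; the pipeline
writes identical artifacts on rerun. The test suite uses cohorts of tens to
hundreds of patients for unit behavior, 6000 patients (2000 per stratum)
for parameter recovery — planted event proportions and analytic mean total
costs are recovered within three standard errors — and 1000 replicates of
a three-stratum null comparison to confirm the χ² test holds its 5% size
(within two binomial standard errors). These sizes give stable checks at a
few minutes of total runtime.

## Known limitations

* Age is computed from birth year only (claims tables rarely carry full
  birth dates), so eligibility at the 18-year boundary is year-resolution.
* Incidence rates use person-years from observed follow-up inside the
  12-month window; the published analysis mentions incidence rates but
  prints only proportions, so the denominator convention is this package's
  choice.
* The default CPI table is the identity; real conversion factors must be
  supplied to reproduce dollar figures on real extracts.
* Episode merging is date-based (gap ≤ 1 day); claims lacking admission /
  discharge spans cannot distinguish a long stay from adjacent stays.
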