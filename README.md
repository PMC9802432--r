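# cdsthru

Claims-based stratification of vedolizumab response probability and
12-month healthcare resource utilization (HRU) in Crohn's disease.

`cdsthru` is an R package for biostatisticians and HEOR analysts working
with longitudinal administrative-claims tables (patients, enrollment spans,
coded medical claims with paid amounts, laboratory results). It implements
the full analysis pipeline around the vedolizumab clinical decision support
tool (CDST):

* **Scoring.** The 5-variable CDST awards +2 points for no prior bowel
  surgery, +2 for no prior fistulizing disease, +3 for no prior anti-TNF
  exposure, +0.4 points per g/L of serum albumin, and a C-reactive-protein
  penalty (0 for CRP < 3 mg/L, −0.5 for 3–10 mg/L, −3 for > 10 mg/L).
  Patients are stratified as high (score > 19), intermediate (> 13 to ≤ 19)
  or low (≤ 13) probability of response. The modified 3-variable CDST keeps
  only the clinical points (attainable scores 0, 2, 3, 4, 5, 7) with high
  defined as > 3 — no laboratory data required.
* **Cohort construction.** Index date at first study-drug claim inside the
  accrual window; eligibility requires age ≥ 18, two Crohn's disease
  diagnoses ≥ 30 days apart before index, and ≥ 6 months of continuous
  enrollment on both sides of index, with an attrition log per criterion.
* **Outcomes.** 12-month CD-related hospitalization, surgery and
  emergency-department (ED) events from diagnosis/procedure/revenue codes
  (ED revenue 0450–0459 and 0981), with the reclassification rule that an
  ED visit followed by hospitalization or surgery counts as that event.
* **Costs.** Claim amounts converted to 2017 USD through a CPI table and
  annualized as `total / (days + 1) × 365.25` when eligibility is shorter
  than 12 months; categories (hospitalization, surgery, ED, office visits
  CPT 99211–99215, endoscopy/scans, laboratory revenue 0300–0319) partition
  every claim exactly once.
* **Inference.** Pearson χ² for event proportions; one-way ANOVA (3 strata)
  or pooled two-sample *t* (2 strata) for annualized costs — each with a
  summary-statistics variant that works from printed (n, mean, SD)
  triplets.
* **Synthetic claims.** `simulate_claims()` generates complete,
  internally consistent claims histories with stratum-dependent risk-factor
  prevalences, event probabilities and right-skewed (log-normal) costs, so
  the whole pipeline is testable without proprietary data. The latent
  stratum ships in a separate truth table that the analysis never sees.

## Worked example

```r
library(cdsthru)

sim    <- simulate_claims(claims_sim_config(n_patients = 500, seed = 7))
cohort <- build_cohort(sim$dataset)
scores <- score_cohort(cohort, "five_var")
scores
#> <cdst_scores> variant = five_var, 475 scored (25 excluded: missing labs)
#> stratum
#>         high intermediate          low
#>          257          186           32

outcomes <- extract_cohort_events(sim$dataset, cohort)
costs    <- aggregate_cohort_costs(sim$dataset, outcomes)
cmp      <- compare_strata(outcomes, costs, scores$scores)
cmp[cmp$variable %in% c("hospitalization", "surgery", "cost_total"), ]
#>         variable      type              high      intermediate
#>  hospitalization     n (%)         49 (19.1)         74 (39.8)
#>          surgery     n (%)         26 (10.1)         46 (24.7)
#>       cost_total mean (SD) 16638.5 (36137.2) 22453.8 (40649.4)
#>                low statistic p_value                    test
#>          13 (40.6)    25.084  0.0000      Pearson chi-square
#>          10 (31.2)    20.835  0.0000      Pearson chi-square
#>  25704.0 (32548.8)     1.739  0.1768 one-way ANOVA (summary)
```

High-probability responders show markedly lower hospitalization (19.1% vs
40.6%) and surgery (10.1% vs 31.2%) rates than low-probability responders,
recovering the association planted by the generator. Scoring a single
patient:

```r
f <- data.frame(patient_id = "pt-001", prior_bowel_surgery = FALSE,
                prior_fistulizing_disease = FALSE,
                prior_anti_tnf_exposure = TRUE,
                baseline_albumin = 38, baseline_crp = 6.2)
score_5var(f)   # 2 + 2 + 0 + 0.4*38 - 0.5 = 18.7 -> intermediate
score_3var(f)   # 2 + 2 = 4                        -> high
```

`verify_published()` recomputes every derivable number of the published
validation-study summary tables (percentages from counts, χ²/ANOVA/t
p-values from counts or summary triplets, the low/high cost ratio) from the
plain-text fixtures bundled under `inst/extdata/` and reports one pass/fail
row per check.

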