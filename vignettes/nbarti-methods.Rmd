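---
title: "Measuring inappropriate antibiotic prescribing for non-bacterial ARTI from claims data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring inappropriate antibiotic prescribing for non-bacterial ARTI from claims data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Most acute respiratory tract infections (ARTI) seen in outpatient care are
viral, so an antibiotic prescription at a consultation where nothing but a
non-bacterial ARTI was diagnosed is, on its face, inappropriate. Claims
databases record every reimbursed consultation, diagnosis and dispensed drug
for millions of covered lives, which makes them the natural instrument for
measuring how often this happens, to whom, and whether it is changing — but
they record *billing* events, not clinical reasoning, and turning them into a
defensible prescribing rate requires a chain of explicit conventions. This
package implements that chain as a tested pipeline:

1. **Cohort extraction.** A consultation is a unique (patient, facility,
   date) triple. Diagnoses are linked to a consultation when issued for the
   same patient within a lookback window (default 30 days, inclusive of the
   consultation day). A consultation is an ARTI consultation when its active
   codes include an ICD-10 class in J00–J06 or J20–J22.
2. **Appropriateness screen.** Each diagnosis code carries a binary verdict
   — does it require antibiotic treatment? — supplied as a lookup table.
   Any consultation with *any* active antibiotic-requiring code is excluded;
   the remainder is the non-bacterial ARTI (NB-ARTI) cohort. The verdict
   table is consumed as data; building one (an expert-panel adjudication) is
   out of scope, and the table shipped with the package is a clearly
   labelled synthetic stand-in.
3. **Outcome linkage.** The outcome is a same-date prescription of an oral
   systemic antibiotic (ATC J01), matched on patient and date because
   pharmacy claims often carry a different facility. J01DD
   (third-generation cephalosporins), J01FA (macrolides) and J01MA
   (fluoroquinolones) are flagged broad-spectrum; J01C are penicillins; all
   other J01 codes form a residual class.
4. **Analysis.** Monthly prescribing rates per 100 NB-ARTI consultations
   (overall and stratified), composition tables, ordinary-least-squares
   trend fits on the month index, a regression of the prescribing rate on
   the NB-ARTI-per-ARTI diagnosis rate, crude and adjusted odds ratios from
   logistic regression, specialty-stratified yearly adjusted ORs, and a
   linkage-window sensitivity sweep.

## Conventions and the reasoning behind them

Several choices are not forced by the data and deserve a paragraph each.

**The consultation unit.** Claims lines repeat (one line per billed item),
so raw lines are collapsed to one consultation per (patient, facility, date)
with a logged count. Collapsing rather than erroring keeps real extracts
usable; the count makes silent inflation of denominators impossible.

**The 30-day linkage window.** Diagnoses persist in claims until a facility
deletes them, so an unbounded join would resurrect stale diagnoses and
deflate the apparent inappropriate-prescribing rate (old bacterial codes
would excuse new prescriptions) while inflating the denominator. The window
caps staleness; it is inclusive at both ends because the typical pattern for
a new ARTI visit is a diagnosis issued on the visit date itself.
`window_sensitivity()` rebuilds the cohort across candidate windows, and two
properties hold by construction and are tested: ARTI selections and
bacterial exclusions are both nondecreasing in the window.

**Age at consultation.** The data store only year and month of birth, so age
is completed years on year-month granularity with birth treated as the 1st.
The nine bins (0–3, 4–6, 7–12, 13–18, 19–29, 30–39, 40–49, 50–59, 60–)
follow the child-healthcare-subsidy brackets that plausibly shift
consultation behaviour; the data cover ages below 75, and an age above 75 is
an error rather than a silently clipped value.

**Hours, holidays, fiscal years.** In-hours is the half-open interval
[08:00, 18:00) on a non-holiday weekday; everything else is out-of-hours.
The holiday calendar is configurable and defaults to weekends only — no
national-holiday table is bundled, because none was specified and shipping a
wrong one would be worse than shipping none. Input may carry either a clock
time or a pre-coded in/out flag, since claims feeds ship the latter. Fiscal
years run April–March and are labelled by the April year.

**Exclusion scope and prescription matching.** Exclusion considers
antibiotic-requiring diagnoses from *any* facility within the window (the
screen is about the patient's clinical state, not the bill), and
prescriptions match on patient + date only. Both are configuration switches
(`same_facility_exclusion`, `match_facility`) because the underlying
convention is genuinely undecidable from the data alone.

**Regression models.** Crude ORs come from single-factor logistic fits, the
adjusted table from one joint fit over sex, age group, insured status,
specialty, facility operation type, visit hours, diagnosis category, fiscal
year and calendar month, with Wald 95% intervals (estimate ± 1.96·SE on the
log scale) — the conventional choice at claims scale, where likelihood
profiling is both infeasible and unnecessary. Fiscal year and month are
only partially collinear because the study year starts in April; the design
matrix is checked for rank and aliased levels are reported, not dropped
silently. Perfect separation is detected before fitting and named. Rows
with missing covariates are dropped with a logged count. Patients
contribute multiple consultations and no clustering adjustment is applied;
this replicates the measurement convention the pipeline targets and is a
known limitation — standard errors for patient-level covariates are
anti-conservative.

**Rounding.** Percentages round half away from zero to one decimal
(`round_half_away()`), matching how composition tables are conventionally
printed; base R's round-half-to-even would disagree on exact .05 boundaries.

**Degenerate inputs.** A zero-variance response in a trend fit returns
slope 0 and R² 0 with a warning (keeping sweep outputs total) rather than an
undefined fit; months with zero denominator are flagged undefined and
dropped from trend fits, not imputed; a relative change from a zero baseline
is an error.

## The synthetic claims world

`sim_config()` / `generate_bundle()` describe one fixed stylised world so
that every stage — including both regression models — is testable without
any external data. What it emulates:

* nine age strata with the consultation-share mix of a large
  employee-insurance population (children dominate);
* five facility operation types × four specialties, with clinics without
  beds carrying ~88% of consultations;
* winter-peaked seasonal visit intensity around a nominal 2 ARTI visits per
  patient-year;
* diagnosis-category mix over the eleven labels the pipeline reports,
  antibiotic-requiring co-diagnoses on 35% of visits (these exit at the
  exclusion stage), decoy requiring diagnoses dated 45 days before a visit
  (outside the default window — they must *not* cause exclusion), finer
  national-code suffixes on a third of codes (exercising prefix lookup),
  and non-J01 decoy prescriptions (which the outcome linkage must ignore);
* a same-date prescription drawn from a logistic model whose covariate
  effects echo published adjusted odds ratios *as stylised parameter
  sources* — the package nowhere claims to reproduce real-data magnitudes —
  plus a secular per-month log-odds trend. The intercept (−1.300311) was
  calibrated once, by exact enumeration, so the default world's mean monthly
  rate over the 63 study months is 31.65 per 100 consultations; the default
  trend (ln 0.678 / 60 per month) is the fiscal-year-2017 adjusted OR spread
  over its 60-month distance from the reference year.

Two structural guarantees make the world *exactly* analysable rather than
approximately so:

1. **Refractory spacing.** Same-patient consultations are thinned to be at
   least 77 days apart. No diagnosis issued for one consultation can then
   fall inside another consultation's linkage window, so the
   diagnosis-category covariate the pipeline derives equals the generated
   one and the prescribing model is exactly true for the analysis dataset.
   The cost is an effective visit rate slightly below nominal, which
   rescales cohort size and nothing else.
2. **Exact time decomposition.** With the study starting in April, the
   month index satisfies `t = 12·(fiscal_year − first_year) +
   ((calendar_month − 4) mod 12)`, so a linear trend in `t` is *exactly*
   representable by fiscal-year and month factors. `ground_truth()`
   therefore provides closed-form true ORs for every term the adjusted
   model fits — including fiscal year and month — and an expected monthly
   rate curve computed by exact enumeration over the finite covariate grid
   (no simulation anywhere in the oracle).

What the world does **not** emulate: employment-based selection and
retirement censoring, within-patient prescribing habits (outcomes are
independent given covariates), episode-of-care structure across visits,
facility-level prescriber effects, and real national-holiday calendars. A
green end-to-end test therefore establishes that the *pipeline* is correct
under its stated conventions, not that any real-world rate is reproduced.

## What the tests establish

* Hand-traced fixture: a 7-consultation toy bundle whose attrition under
  windows 0/7/30/60 was computed by hand before implementation.
* Brute-force oracle: on small bundles, the cohort builder is compared
  triple-by-triple against a naive implementation that scans every
  (consultation, diagnosis, prescription) combination.
* Closed-form oracles: crude logistic ORs against 2×2 cross-products (6
  significant figures over random tables); OLS slopes against
  Σ(t−t̄)(y−ȳ)/Σ(t−t̄)² to 1e-10; composition percentages against printed
  published counts.
* Statistical recovery: on a *balanced* measurement-design configuration
  (every covariate level ≥ ~9% mass — chosen a priori so each coefficient
  carries enough information; with the realistic mix, a 0.4%-share facility
  type cannot be pinned to ±10% at any desk-scale n), the full claims →
  cohort → adjusted-model path recovers every true OR within ±10% at
  n ≈ 2×10⁵, and 95% Wald intervals cover truth at 0.95 ± 0.03 across 200
  replicates of n = 50,000.

Two published composition cells (J06 28.949% printed as 29.0, J03 2.746%
printed as 2.8) are arithmetically inconsistent with their own printed
counts; the tests assert the correct recomputation for those two and exact
agreement for the other 36.

## Worked example

```{r, eval = FALSE}
library(nbarti)

cfg <- sim_config(n_patients = 4000)         # the default stylised world
bundle <- generate_bundle(cfg, seed = 1)
cohort <- build_cohort(bundle, builtin_appropriateness("lenient"))
attrition(cohort)

rates <- monthly_rate(cohort)
fit_trend(rates)                              # slope per month, p, R^2
relative_change(rates, 0, 62)                 # endpoint change, %
or_table(cohort)                              # crude + adjusted ORs
window_sensitivity(bundle, builtin_appropriateness("lenient"),
                   windows = c(0, 7, 30, 60))
```

The same run, file-based and reproducible, via the pipeline:

```{r, eval = FALSE}
run_pipeline(list(simulate = list(n_patients = 4000, seed = 1),
                  out_dir = "out", windows = c(0, 30)))
```
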