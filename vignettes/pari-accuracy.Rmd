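---
title: "Validating the persistent AKI risk index: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating the persistent AKI risk index: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pariscore)
library(dplyr)
```

## The clinical question

Acute kidney injury (AKI) complicates a large share of intensive-care
admissions, and patients admitted for acute respiratory failure are at
particular risk through lung–kidney crosstalk. The *renal angina* idea is
that small, early perturbations — a modest creatinine drift over the first
day, hyperbilirubinemia, sepsis, the need for ventilatory or hemodynamic
support — flag patients whose kidneys are about to fail before KDIGO
criteria are met. The **persistent AKI risk index (PARI)** quantifies this:

\[
\mathrm{PARI} = w(\Delta\mathrm{Cr}) \times
  \big(2\,[\mathrm{hyperbilirubinemia}] + 2\,[\mathrm{sepsis}] +
       4\,[\mathrm{MV\ or\ VAD}]\big)_{\;\vee 1}
\]

where \(\Delta\mathrm{Cr}\) is the serum-creatinine change over the first
24 ICU hours and the multiplier \(w\) is banded: \(<0.2\) mg/dL scores 1,
\(\ge 0.2\) scores 2, \(\ge 0.3\) scores 4, \(\ge 0.4\) scores 10. When no
condition is present the condition sum is taken as 1. Bands are closed on
the left (a delta of exactly 0.3 scores 4), and negative deltas fall in the
lowest band — observed cohorts have a delta-creatinine interquartile range
straddling zero, so this matters in practice.

Exhaustive enumeration of multiplier × condition-sum products gives a
14-value support with maximum 80. The 13-value list usually cited for the
index omits \(4 \times (2+2+4) = 32\) even though the published weights
admit it; `enumerate_pari_support()` returns all 14 values and flags 32 in
an attribute rather than silently following either convention.

This package evaluates PARI as a *diagnostic* instrument: given
longitudinal ICU records it computes the score, stages AKI by KDIGO,
derives four endpoints (AKI within 72 h, persistent AKI, RRT and death
within 7 days), and compares PARI against delta creatinine, SOFA and
APACHE II with correlated-ROC machinery.

## Operationalizing the clinical definitions

**Day grid.** Daily records are indexed from admission; the measurement
taken at hour \(24d\) defines day \(d\), so day 0 is admission, day 1 the
24-hour record and day 3 the 72-hour record. "Within 72 h" is the maximum
stage over assessments on days 0–3 (the day-3 record being the 72-hour
boundary). The mandatory renal records — creatinine, urine output and RRT
status at admission, 24 h and 72 h — are therefore days 0, 1 and 3.

**Baseline creatinine** is the admission (day-0) value. Staging needs a
reference and admission is the only anchor universally available once known
chronic kidney disease has been excluded; premorbid outpatient creatinines
are not part of the record.

**KDIGO staging.** Each day is staged by the maximum over three criterion
families: creatinine ratio to baseline (1.5–1.9× → stage 1, 2–2.9× → 2,
≥3× → 3), absolute creatinine (a ≥0.3 mg/dL rise within any 48-h window →
stage 1; a level ≥4 mg/dL → stage 3), and urine output (<0.5 mL/kg/h for
6–12 h → 1, for ≥12 h → 2; <0.3 mL/kg/h for ≥24 h or anuria ≥12 h → 3),
with RRT forcing stage 3. Urine output is supplied as sub-daily windows
(default four 6-h blocks); consecutive qualifying windows accumulate
duration, including across midnight, and runs are broken at patient
boundaries. The 48-h rise window uses the previous two day records of the
same patient.

**Sepsis** is flagged when SOFA rises by ≥2 points over the first 24 h and
the patient is on antibiotics on both of the first two daily records
(≥48 h from admission). Counting antibiotics from admission, rather than
over any later 48-h span, is an interpretation we fixed once and note here:
the admission-anchored reading matches how the score's other conditions are
assessed.

**Persistence.** "Stage 2–3 for more than 72 hours" on a daily grid is
implemented as **at least 4 consecutive daily assessments** at stage ≥2,
beginning on or before day 7. Persistence may begin after 72 h, so a
persistent patient need not have AKI within 72 h; cohorts can legitimately
show more persistent-AKI cases than 72-hour cases.

**Eligibility.** Records are excluded, with one reason each, in this order:
missing mandatory renal data; ICU stay under 72 h (applied to alive
discharges — every early death also has a short stay, so deaths before
72 h fall under the death rule); death before 72 h; any screening
creatinine above 4 mg/dL; known chronic kidney disease. The screening
window for the creatinine rule is admission through 72 h: stage-3 values
≥4 mg/dL occurring later clearly appear in retained patients. Mandatory
record checks only consider times the stay reached, so a 48-hour stay with
complete data is a short stay, not missing data. The audit log lists every
input record, and retention is permutation-invariant.

**Missing data.** Missing bilirubin counts as no hyperbilirubinemia and
missing MV/VAD flags as no support — both conservative toward a lower
score, and rare in the data this emulates (hyperbilirubinemia ~0.7%).
Patients without a SOFA at admission or 24 h are scored non-septic; the
number of such fallbacks is reported as attributes of `score_patients()`.
Creatinine missing at admission or 24 h makes the score undefined — those
patients are exactly the ones the eligibility filter removes. The RRT
outcome is `NA` (not `FALSE`) when RRT status is unrecorded on some day of
the 7-day window and never positive; accuracy analyses drop missing
outcomes pairwise, so different outcomes can have different denominators.

## The accuracy layer

The empirical AUC is the tie-corrected concordance probability computed by
midranks; its variance and the covariance between two predictors on the
same patients come from DeLong placement values, giving the paired test
\(z = (\hat A_a - \hat A_b)/\sqrt{v_a + v_b - 2c_{ab}}\) with a two-sided
normal p-value. Identical predictors short-circuit to \(p = 1\); a zero
variance of the difference with unequal AUCs is an error rather than a
silent infinity. AUC confidence intervals are
\(\hat A \pm 1.96\sqrt{v}\), clipped to \([0,1]\).

Cutoffs use the "positive if score ≥ c" convention. The Youden-optimal
cutoff maximizes \(J = \mathrm{se} + \mathrm{sp} - 1\) over the distinct
observed scores — only observed values can change the empirical \(J\), so
that scan is an exhaustive search over all real thresholds — with ties
broken toward the smallest cutoff. The 2×2 metrics (sensitivity,
specificity, PPV, NPV, accuracy) are percentages with **Wald** 95%
intervals on each metric's own denominator, clipped to \([0,100]\); Wald
(not Wilson or Clopper–Pearson) is used because back-calculating published
cutoff tables of this kind reproduces their printed intervals exactly. A
metric with an empty denominator (no test-positives, say) is `NA`, not 0.
Point estimates are reported at full precision; report writers round to
one decimal for display parity. p-values are two-sided with no
multiple-testing correction.

## What the synthetic cohort emulates

No patient-level data ship with the package, so every stage is exercised
against `generate_cohort()`. Each patient draws a latent 7-day
renal-trajectory class — `none`, `transient` (stage ≥2 within 72 h that
resolves), `persistent_early` (a qualifying run starting within 72 h),
`persistent_late` (the run starts on days 4–7) — and the class fixes a
multiplicative creatinine drift profile over baseline (peaks at 2.4–2.6×),
the day-1 multiplier distribution (hence delta creatinine and the PARI
band), oliguric days, RRT assignment (within persistent classes) and the
7-day death hazard. This latent-class coupling, rather than per-variable
independence, is what makes AKI, RRT, death, support flags and high PARI
co-occur the way between-group tables in real cohorts show.

Default marginal rates are those of the analyzed population this package
targets: 17.1% AKI within 72 h, 19.5% persistent AKI with 56% of runs
starting within 72 h, 5% RRT, 12.6% 7-day death (with 33.7% death given
early AKI, and the no-AKI rate derived to match the marginal), 81.6%
COVID-19, admission creatinine log-normal with median 0.88 mg/dL, MV/VAD
at 47.8%/27.2% given early AKI versus 22.6%/16.4% without, antibiotics
60.8%, hyperbilirubinemia 0.7%. Where no source value exists (noise scales,
the day-1 multiplier spread, oliguria share), values were chosen once for
clinical plausibility — e.g. 8% day-to-day multiplicative creatinine noise,
a log-normal day-1 multiplier with median 1.25 for early-AKI classes so
that PARI's AUC for 72-hour AKI lands in the 0.7–0.8 range typical of
published validations — and are exposed as `sim_config()` knobs.

Two design points deserve emphasis. First, the generator emulates the
*post-eligibility* population (whose rates the targets describe), so
creatinine paths are rejection-sampled until no screening value (days 0–3)
exceeds 4 mg/dL; `inject_exclusion_violations()` then adds screen-failing
records explicitly, each violating exactly one rule and tagged with the
intended reason for filter audits. Second, persistent-late patients are
given no 7-day death: their qualifying run ends after day 7, so an earlier
death would make the class label unobservable by construction.

What the simulator does **not** model: hospital-level clustering, insurance
strata, COVID-specific renal dynamics beyond a covariate, nephrotoxic
pharmacology, informative missingness, or measurement error in SOFA/APACHE
II (both generated directly as integers, consistent with their role as
given inputs). Passing tests on this cohort therefore demonstrate that the
pipeline implements its definitions correctly and recovers known
parameters — not that PARI performs at any particular level in new
clinical populations.

## Numerical and degenerate-input choices

* Banding and staging use half-open bands, closed on the qualifying side,
  matching the "≥" phrasing of the definitions.
* Single-class label vectors, empty metric denominators and zero-variance
  AUC differences raise typed errors (`pariscore_error_*`) instead of
  returning boundary numbers.
* The day grid may contain gaps; the 48-h rise criterion only uses prior
  records at most two days back, and persistence runs treat unassessable
  days (`NA` stage) as breaks.
* All randomness flows from one integer seed; the same configuration is
  bit-reproducible, which the tests assert.

## Problem sizes used by the tests

The unit suite works on hand-built fixtures of a few patients. The
parameter-recovery check runs the full pipeline at 10,000 patients (three
binomial standard errors around each configured rate); oracle equivalence
of the AUC uses 500 random instances up to n = 200 against pairwise
enumeration; the paired DeLong test is cross-checked against a 10,000-rep
stratified paired bootstrap on 200 instances of 100 patients, written
against precomputed concordance kernels with multinomial weights so the
oracle is exact and fast; and the published-cutoff-table reconstruction
rebuilds 538-patient fixtures from printed 2×2 counts. These sizes were
chosen so each check has real statistical teeth while the whole suite runs
in well under a minute.

## A worked example

```{r example}
cfg <- sim_config(n_patients = 400, seed = 2020)
cohort <- inject_exclusion_violations(generate_cohort(cfg), fraction = 0.15)
analysis <- analyze_cohort(cohort$admission, cohort$daily)
analysis$n_analyzed
analysis$suite$auc |> filter(predictor == "pari")
analysis$suite$youden
confusion_at_cutoff_demo <- analysis$suite$cutoffs |>
  filter(outcome == "aki_72h", cutoff == 4)
confusion_at_cutoff_demo
```

## Known limitations

The persistence definition (≥4 consecutive daily assessments) is one
defensible discretization of "more than 72 hours"; sub-daily staging would
shift borderline cases. Admission-anchored baselines understate staging in
patients admitted with creatinine already elevated above their premorbid
value. The Wald intervals can degenerate near 0% or 100% with small
denominators — they are reported for parity with the published analyses
this package is designed to reproduce, not because they are the best
interval. And the simulator's dependence structure is a modeling choice:
its joint distributions are documented knobs, not estimates from data.
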