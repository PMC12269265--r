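---
title: "Methods: claims-based sepsis surveillance, the synthetic cohort, and the statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: claims-based sepsis surveillance, the synthetic cohort, and the statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsisclaims)
```

## The surveillance problem

Nationwide inpatient claims databases such as Japan's DPC system cover the
large majority of acute-care admissions but record no laboratory values, so
consensus sepsis definitions that rest on SOFA scoring cannot be applied.
Surveillance in such data instead uses an *operational* phenotype built
from orderable, billable facts: blood cultures, intravenous antibiotic
days, vasopressors, organ-support procedures and ICD-10 diagnosis codes.
This package implements that phenotype, the statistics layered on it, and a
synthetic claims generator that makes the whole pipeline testable without
any protected data.

## Data model

Three tables describe a cohort. Admissions carry demographics, admission
year, length of stay (LOS) in integer hospital days with day 1 = admission
day, an in-hospital death flag with the death day, ICU day sets and a
maintenance-dialysis flag. Diagnoses carry ICD-10 codes; events carry dated
blood cultures, IV antibiotic administrations (with an agent identifier),
vasopressors, ventilation/oxygen, renal replacement therapy (RRT) and
hydrocortisone. Calendar dates are never needed beyond the admission year:
every within-stay rule operates on hospital days, matching how claims data
aggregate drug administrations to calendar days. Files are UTF-8 CSV with
fixed headers and empty fields for missing values; `read_claims()` enforces
row invariants and referential integrity with row numbers in every error.

## The case definition, rule by rule

**Presumed serious infection.** A blood-culture day $c$ and a *new* IV
antibiotic starting on day $s$ with $|s-c| \le 2$, followed by IV
antibiotics on at least four consecutive calendar days; a patient who dies
before the fourth day of therapy qualifies provided antibiotics continued
through the day of death. Where several (culture, start) pairs qualify, the
earliest is reported — smallest culture day, then smallest start day.

Three operational details are genuinely open in a calendar-day claims
setting, and we fixed them as follows:

* *"New" antibiotic.* An agent counts as newly initiated on day $s$ if it
  was not administered on days $s-2$ or $s-1$ of the same admission. The
  2-day lookback mirrors the ±2-day culture window; it is a configurable
  argument (`lookback`).
* *Agent switches.* The four-day run may be sustained by any IV antibiotic
  (switching agents mid-course is common practice); a calendar day with no
  IV antibiotic breaks the run. A `strict` single-agent mode is available.
* *Death exception.* Applied only to in-hospital death (not discharge),
  only when death falls before day $s+3$, and only when antibiotics were
  given on every day from $s$ through the death day — one antibiotic dose
  followed by unrelated withdrawal of therapy days before death should not
  qualify an infection.

**Acute organ dysfunction.** Circulatory = any vasopressor event;
respiratory = any ventilation or oxygen-therapy event; renal = any RRT
event *unless* the patient is on maintenance dialysis (chronic dialysis is
not acute renal failure); hepatic dysfunction, thrombocytopenia,
coagulopathy and acidosis from ICD-10 prefix sets. The shipped prefix sets
are clinically plausible placeholders (K72, D69.5/D69.6, D65, E87.2, and
standard comorbidity/infection-focus blocks); a production analysis should
substitute locally validated lists via the YAML config
(`read_code_lists()`). Prefix matching is the default ("K72" matches
"K720"), exact matching is available.

**Sepsis, shock, onset.** Sepsis = infection ∧ (≥ 1 dysfunction). Septic
shock = sepsis ∧ ≥ 1 vasopressor event — so shock implies the circulatory
category by construction, which is intentional and mirrors how
vasopressor-based shock definitions behave. Community onset = sepsis with
both culture and antibiotic start on hospital days 1–2; calendar-day data
cannot resolve 48 hours more finely, and a sepsis episode whose reported
(earliest) window starts later is hospital-onset by definition.

**Deduplication.** Mortality and deaths-per-1,000 analyses count each
patient once: among a patient's sepsis admissions the earliest by
(admission year, admission id) is kept, and the patient contributes to the
kept admission's year. LOS and proportion analyses deliberately use all
admissions — each hospitalization is a unit of resource use.

**The oracle.** `classify_oracle()` re-evaluates every rule literally: it
builds the full day-by-agent administration grid and enumerates every
(culture event, antibiotic event) pair. It shares no code with the
production path and exists so the test suite can demand exact agreement on
hand-built fixtures and thousands of randomized admissions.

## The synthetic cohort

The generator draws, per admission: year (2010–2020), age (normal,
mean 74, SD 14, truncated to 18–104), sex (55% male), BMI (normal,
mean 21.6, SD 4.2, 5% missing), eight independent comorbidity flags at the
prevalences seen in large sepsis cohorts (hypertension 29.6% … chronic
renal failure 5.1%), true sepsis status (baseline 5.4% at mid-period with a
+0.05/year logit drift), shock among sepsis (14.7%), ICU admission (50.7%
in shock, 19.2% in non-shock sepsis, 3% otherwise), in-hospital death from
a logistic model (intercept logit(0.20); shock +0.83 log-odds; −0.041 per
year, i.e. OR 0.96/year; +0.025 per year of age; male +log 1.15; ICU −0.10;
malignancy/chronic renal/heart failure +0.26/+0.18/+0.18), and LOS from
log-normal distributions per shock × survival stratum (e.g. shock
survivors: median 45 days, σ = 0.85) with a −0.02/year location drift.
Non-sepsis admissions get a flat 2% mortality. Community onset rises on the
logit scale by +0.06/year from 43.4% (shock) / 63.2% (non-shock) at
mid-period.

Conditional on true status the generator emits events that *satisfy* the
phenotype — culture day, qualifying antibiotic course (≥ 4 days, with agent
switches in ~30% of courses, truncated by death for the death-exception
pathway), at least one dysfunction marker, vasopressors for shock — and
emits **near-miss negatives** at configurable rates among non-sepsis
admissions: cultures with no antibiotics, courses starting 3 days after the
culture, 3-day survivor courses, and RRT under maintenance dialysis with a
qualifying infection but no other dysfunction. Near-misses exist to stress
the engine; they must classify negative, and the tests assert that
sensitivity and specificity against ground truth are exactly 1.

Design choices worth stating explicitly:

* Non-survivors die on their final hospital day (`death_day = los_days`):
  claims stays end at death, and events after death would corrupt the
  death-exception rule. (A uniform death day inside the stay was
  considered and rejected for exactly that reason.)
* One seeded RNG stream with all draws in a fixed, documented vectorised
  order; identical configs are byte-identical, distinct seeds differ.
* Comorbidities are drawn independently — published tables give marginal
  prevalences only, and no joint distribution is identifiable from them.
* Readmissions: ~10% of admissions are second admissions of an existing
  patient (paired within sepsis and within non-sepsis separately so
  deduplication has real work to do).
* Out-of-window and short-course near-misses are generated as survivors so
  the death exception can neither rescue nor truncate them.

What the generator does **not** emulate: antibiotic spectra and pathogen
biology, hospital-level clustering, seasonal effects, coding error, or the
COVID-period case-mix shift. Passing tests on synthetic data therefore
demonstrate the *correctness of the machinery* under the stated generative
assumptions, not the accuracy of the case definition against clinical
reality — the latter is a validation question requiring chart review.

## Statistics

* **Proportions** use the Wilson score interval (stable at 0/n and n/n;
  published surveillance figures show CI bars without naming a method, and
  Wilson is the standard default); a Wald option exists.
* **Deaths per 1,000 inpatients** = deduplicated sepsis deaths ÷ *all*
  screened admissions × 1,000. The denominator choice is verified
  arithmetically: 833,815 / 82,170,094 × 1,000 = 10.15 reproduces the
  published overall rate, and the shock/non-shock components (2.59, 7.56)
  add to it exactly under the shared denominator.
* **Quartiles** interpolate linearly between order statistics
  (`quantile type 7`); IQR conventions differ across software, so the rule
  is part of the contract (e.g. {10, 20, 30, 40} → median 25,
  IQR 17.5–32.5).
* **Cochran–Armitage** is implemented from its score form with calendar
  years as scores; it is invariant under affine score rescaling, and the
  tests cross-check it against `stats::prop.trend.test` and against the
  exact conditional (multivariate hypergeometric) permutation distribution
  on a small series.
* **Linear trends** are unweighted OLS of the yearly summary on calendar
  year — yearly values enter with equal weight, matching the slope/R²
  presentation style of surveillance reports; a weighted mode exists. A
  constant series returns slope 0, R² 0 rather than NaN.
* **Two-group comparisons**: chi-square without continuity correction
  (appropriate at claims-scale counts; correction available), Welch's t,
  Mann–Whitney with tie-corrected normal approximation (exact only for
  n ≤ 20 without ties). Expected cells below 1 raise a warning.
* **Logistic regression** is fitted by IRLS (Newton scoring) with
  step-halving, which makes the log-likelihood provably non-decreasing;
  convergence when the largest score component < 1e-8 or the relative
  log-likelihood change < 1e-10; hard failure after 100 iterations.
  Covariates are internally centred so the working intercept is the
  log-odds at covariate means — without this, calendar-year covariates put
  the raw intercept in the tens and break any magnitude-based divergence
  heuristic. A coefficient passing |15| on the centred scale raises a
  separation error. Wald SEs come from the inverse observed information;
  ORs are per covariate unit, so the year term is the adjusted OR per
  admission year. Categorical covariates take their most frequent level as
  reference; missing covariates are dropped as complete cases with a
  recorded count. The adjusted-mortality wrapper additionally drops binary
  covariates whose outcome cross-tabulation has an empty cell — in small
  strata such covariates quasi-separate and carry no stable estimate.

## Calibration studies and problem sizes

The package ships two simulation studies, run by the test suite and the
acceptance script at sizes chosen to finish on a desk machine while keeping
the Monte-Carlo error meaningful:

* *Trend-test calibration*: 11 years × 5,000 admissions/year × 100 seeds.
  Under a flat 40% mortality null the rejection rate at α = 0.05 estimates
  the type-I error; under a linear 46.7% → 33.2% decline (the magnitude
  reported for septic shock nationally) it estimates power.
* *OR recovery*: 100 replicates × 200,000 admissions, cohort mode; the
  per-year OR is refit by IRLS on the ground-truth sepsis cohort
  (≈ 10,800 admissions per replicate, with shock as a covariate — the
  mortality model carries a single secular coefficient, so this parameter
  is the per-year OR in the shock stratum and everywhere else) using the
  correctly specified covariate set, and Wald 95% CI coverage of the true
  OR 0.96 is recorded. The cohort-level fit keeps roughly 300 events per
  parameter, where Wald intervals are essentially nominal; a fit
  restricted to the ~1,600-row shock stratum (~75 events per parameter)
  was examined and is noticeably noisier without changing the conclusion.
  Replicate seeds are drawn from the base seed *through the RNG* rather
  than as consecutive integers: Mersenne-Twister streams initialised from
  consecutive small seeds are measurably correlated, which we observed as
  overdispersion of window-level coverage estimates (windows of 100
  consecutive seeds ranging from 0.89 to 0.98 where scattered seeds sit
  at 0.95–0.98).

## Limitations

The phenotype inherits every limitation of treatment-based surveillance:
vasopressor-defined shock misses vasopressor-sparing practice and
misclassifies non-septic vasopressor use within an infection episode;
code-based dysfunction categories depend on local coding habits; the
placeholder ICD-10 lists must be replaced for any real analysis. The
synthetic cohort is a testbed, not an epidemiological claim — its
parameters are set to published national magnitudes, but agreement of the
pipeline's output with those magnitudes on synthetic data validates the
plumbing, not the biology. Z-statistics and regression slopes at
full-national scale are not reproducible from synthetic desk-scale runs
and are deliberately out of scope; the calibration studies cover the
statistical behaviour of those tests instead.
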