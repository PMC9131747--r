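---
title: "Methods: a Markov cohort model for LDCT and biomarker-based lung cancer screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort model for LDCT and biomarker-based lung cancer screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcscreen)
```

## The decision problem

Low-dose computed tomography (LDCT) reduces lung cancer mortality in heavy
smokers but produces many false-positive findings, each triggering costly and
anxiety-inducing workup. A plasma micro-RNA signature classifier (MSC) can be
used as a triage test on LDCT-positive nodules: the two-test sequence trades
sensitivity (0.69 jointly, versus 0.79 for LDCT alone) for much higher
specificity (0.96 versus 0.81). `lcscreen` implements a cohort
state-transition (Markov) model that compares eight screening policies —
{LDCT alone, LDCT + MSC} × {annual, one-time} × {20, 30 pack-year
eligibility} — on lifetime discounted cost (CNY, 2018 prices), life-years and
QALYs, from a health-care-sector perspective with 100% screening adherence.

## Model structure

Twelve health states: `Normal`, carcinoma in situ (`CIS`), invasive stages
`I`–`IV`, one post-treatment *maintenance* state per stage (periodic
follow-up, accruing 10% of the stage's treatment cost per year), and `Death`
(absorbing). Cycle length is 1 year; cohorts enter between ages 50 and 74 and
are followed to age 79 (the modelled life expectancy), with both costs and
effects discounted at 5% per year (effect discounting can be disabled).

Within a cycle, the fixed event order is: payoff accrual on start-of-cycle
occupancy, then the screening overlay (which splits this cycle's incident
cancers between the screen-detected and clinical pathways and prices the
cycle), then the transition. Cycle 0 is undiscounted. One-off costs —
prediagnostic workup + biopsy at diagnosis and the stage's full treatment
cost — attach to the entry flows of the cycle in which the transition
happens. No half-cycle correction is applied by default (the source analysis
does not mention one); `options$half_cycle_correction` enables the standard
correction.

Key structural choices, made where the published description is silent:

* **Diagnosis coincides with stage entry.** There is no latent undiagnosed
  compartment; detection is parameterized through stage-at-detection
  proportions (screen-detected cancers follow the tool's published stage
  profile, clinically presenting cancers a later-stage profile), not through
  sojourn times.
* **Stage rows use stage-specific death instead of background mortality.**
  The published within-stage death probabilities are all-cause risks;
  adding background mortality on top would double count. Maintenance states
  face background mortality only and are quasi-absorbing (an optional
  recurrence probability, default 0, reopens the stage pathway).
* **Incidence is banded to ages 50–74.** The published incidence table stops
  at 74 and screening has stopped by then; beyond 74 the model generates no
  new cancers. This affects every strategy equally.
* **Rates become probabilities by direct division** (per-100,000 rate /
  100,000), the rare-event approximation; `options$rate_conversion =
  "exponential"` switches to `1 - exp(-rate)`. At these magnitudes the two
  differ by < 0.5%.

## The population and eligibility

The simulated population (default: eight cohorts of 10,000 entering in 2021
with birth years evenly spaced 1947–1971, i.e. 80,000 people aged 50–74) is a
fixed mixture of three smoking strata: ≥ 30 pack-years (12% of the
population, incidence relative risk 3.87), 20–30 pack-years (8%, relative
risk implied by pooling consistency so that the whole ≥ 20 pack-year group
keeps its published RR of 2.84; 1.295 at the default fractions), and the
remainder (RR 1). A strategy chooses *which strata are screened* — nothing
else — so every strategy, and the no-screening sentinel, runs on the
identical population.

This deliberately departs from the simpler reading in which each strategy's
"eligible fraction" carries the elevated risk and the remainder reverts to
baseline: that construction gives each strategy a different total disease
burden, and it breaks the engine invariant (which this package enforces in
its tests) that a strategy with zero sensitivity and zero test costs must
reproduce the no-screening arm exactly.

The stratum fractions (0.20 at ≥ 20 py, 0.12 at ≥ 30 py) are **package
fixtures**: the source analysis used smoking-exposure rates from the
literature without printing them. They are configurable in the parameter
file. In probabilistic analysis, independent draws of the two relative risks
can imply a 20–30 py RR below 1; it is floored at 1 so that risk stays
monotone in smoking exposure.

## Screening mechanics and costs

In a screening cycle, all `Normal` occupants of a screened stratum are
tested. Of the cycle's incident cancers, a fraction equal to the (joint)
sensitivity is screen-detected and enters stages per the tool's
stage-at-detection vector; the rest — and all incident cancers of
unscreened strata or non-screening cycles — present clinically. The default
clinical presentation-stage vector is another labelled fixture (the LDCT
vector shifted one stage later), because the source never prints one.

Costs per screened person and cycle: the LDCT scan (CNY 245.86); for the
conjunctive strategy the MSC assay (CNY 400) charged only to LDCT-positive
screenees (positivity computed from LDCT-alone operating characteristics,
while final classification uses the joint sensitivity/specificity — the
triage reading of the two-test sequence); prediagnostic workup (CNY 628.36)
for false positives (whether false positives also receive biopsy is the
`options$fp_workup` lever, default off); and prediagnosis + biopsy
(CNY 1232.44) plus full stage treatment cost at every diagnosis, screen-
detected or clinical. Annual strategies screen every cycle up to the stop
age of 74; one-time strategies screen at cycle 0 only; follow-up of
diagnosed cases always continues to the horizon.

## Outcomes, dominance and uncertainty

Life-years count the discounted alive fraction per cycle; QALYs weight
occupancy by state utilities (Normal 1.0 — the source reports that
indeterminate screening results did not affect quality of life — cancer
stages 0.75–0.87, maintenance states inheriting their partner stage's
utility, another configurable fixture). ICERs divide incremental cost by
incremental QALYs against the 2021-guideline comparator (strategy 0);
cheaper-and-more-effective strategies are *dominant*, and the efficiency
frontier removes strictly and extended-dominated strategies until
incremental ICERs strictly increase. Cost-effectiveness acceptability curves
count PSA draws with positive net monetary benefit, which subsumes
ICER-below-threshold counting and handles dominant draws (negative
incremental costs) unambiguously; a literal signed-ICER counting mode is
available for comparison. The willingness-to-pay anchor is China's 2018
per-capita GDP, CNY 70,892/QALY, with 3× (CNY 212,676) as the upper bound.

One-way sensitivity sweeps vary screening and maintenance costs and the CPI
rate by ±30%, the discount rate over 0–8%, and the four operating
characteristics over their published ranges, with 11 grid points by default;
the tornado table ranks parameters by ICER bar width. The CPI rate is a
recognised no-op in the base model (shipped costs are already at 2018
prices; the rate applies only when re-basing user-supplied costs), so its
bar has zero width — it is retained because the published univariate
analysis lists it. PSA draws every uncertain parameter independently — beta
for probabilities and utilities, gamma for costs and (departing from the
published table, which lists beta for quantities above 1) the relative risks
— re-validating and renormalizing simplex-valued vectors after element-wise
draws. The published supplement with exact standard errors is unavailable;
defaults are se = 25% of the mean for costs, the published one-way range
divided by 2 × 1.96 for test characteristics, and 10% of the mean otherwise,
all overridable. Threshold search brackets and bisects a monotone
ICER-versus-parameter curve to 1 CNY/QALY or 1e-6 parameter tolerance, after
a coarse monotonicity check.

## Verification strategy, and what a green test establishes

The engine is verified against two independent oracles that share no code
with it: the fundamental matrix `(I − βQ)^{-1}` of random absorbing toy
chains (agreement within 1e-10) and a 100,000-path first-order
microsimulation (agreement within 3 Monte-Carlo standard errors). Every
transition matrix over the full age × sex × strategy grid is checked
row-stochastic to 1e-12, and every cohort trace conserves mass to 1e-10 with
monotone death occupancy. The package's ICER and dominance routines
reproduce, from the *printed* cost/QALY columns of the published base-case
table, the printed ICERs of the age-60 and age-65 strategy-2 rows to within
their 2-decimal rounding, and the printed dominance footnotes in every
start-age block.

What a green suite does **not** establish is numeric reproduction of the
published outcome table itself. The original model was built in a
proprietary GUI environment, and several load-bearing mechanisms are
unpublished: the eligible-smoker fractions, the presentation-stage
distribution of clinically detected cancers, the depth of false-positive
workup, and the PSA standard errors. Under this package's fixed-population
comparison and fixture defaults, widening eligibility from 30 to 20
pack-years (strategy 2) adds QALYs but also adds cost (ICER ≈ CNY 200,000
per QALY at the default fractions) rather than saving money as the published
table reports; the published dominance of the 20 pack-year strategies is
consistent with a comparison in which the 20 pack-year cohort is simulated
as a *different, on-average-healthier population* rather than as added
screening coverage on the same population. The conjunctive annual strategy
(6) is dominated here because its published stage-at-detection profile is
*later*-stage than LDCT alone (27.9% versus 5.6% stage IV), so its detected
cancers cost more and yield fewer QALYs, while the MSC assay adds cost —
its advantage (fewer false positives) is too small at the default workup
price to compensate. These discrepancies are reported by the acceptance
suite as a qualitative finding, not hidden by recalibration.

## Numerical conventions

Tolerances: row-stochasticity 1e-12 at assembly (hard error, never silent
renormalization); trace mass drift 1e-9 aborts a run; simplex inputs 1e-9.
Ties on the efficiency frontier (equal cost and QALYs) break by lower
strategy id. Degenerate inputs: a distribution with zero standard error is a
point mass of any family; a sweep whose substituted value invalidates the
parameter set names the offending grid point; bisection refuses
non-bracketing targets and non-monotone curves with a diagnostic rather than
returning a value. All random processes (toy chains, microsimulation, PSA)
are seed-deterministic, with PSA draws index-seeded (`seed + iteration`) so
that any execution order reproduces the identical sample stream.

## Known limitations

Screening uptake and adherence (assumed 100%), radiation-induced secondary
cancers, and smoking-cessation behaviour change are outside the model, as in
the source analysis. Undiagnosed dwell time is not modelled, so lead-time
bias cannot be represented. Table-2-scale cost magnitudes are not
reproducible from the printed inputs alone (see above). The maintenance
pathway has no recurrence by default, which is optimistic for late stages.
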