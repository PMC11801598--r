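---
title: "Model and methods: a Markov cohort cost-effectiveness engine for type 2 diabetes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2dcea)
```

## The model

`t2dcea` is a deterministic two-arm cohort model with annual cycles. A
cohort defined by its mean baseline profile (age 61, diabetes duration
14.1 years, HbA1c 8.3 %, BMI 35.9 kg/m², SBP 141.5 mmHg, ...) is propagated
through eight **parallel Markov sub-models**: eye disease (none →
background retinopathy → proliferative retinopathy / macular edema / both →
severe vision loss), lower-extremity disease (neuropathy, peripheral
vascular disease, amputation), renal disease (micro- → macroalbuminuria →
ESRD), ischaemic heart disease, myocardial infarction and stroke (each with
first event → history → subsequent event → history-of-subsequent), heart
failure, and mortality. Severity never remits: transition graphs only move
forward, except that history states may re-enter a "subsequent event"
state.

Parallelism is an independence approximation: the chains share nothing but
the covariate vector and survival. Occupancy is therefore stored
*conditional on being alive* (each chain sums to 1) next to a scalar alive
mass. Cross-products between chains (e.g. the joint probability of ESRD
*and* heart failure) are implicitly treated as independent; costs and
utility decrements are additive across chains, which is exactly the
convention additive decrement catalogs assume.

### Cycle anatomy

1. Evaluate background (non-event) mortality on start-of-cycle covariates
   and remove that mass first.
2. Build each sub-model's transition matrix from its risk equations and
   propagate survivors. Inflows into a state in this cycle are its
   *incident events*.
3. Incident MI and stroke events carry an event-year case fatality
   (defaults 0.22/0.32 first/subsequent MI, 0.18/0.28 stroke). These deaths
   form the cardiovascular mortality stream. A fatal event still accrues
   its event cost — care is delivered in the event year — but no state
   cost or QALYs.
4. Accrue costs and QALYs on end-of-cycle occupancy times the end-of-cycle
   alive mass: the dead contribute nothing from their cycle of death
   onward.
5. Advance age and duration by one year, apply next cycle's risk-factor
   path values, and fold the updated history prevalences (fraction of the
   alive cohort with prior MI, stroke, HF, ESRD, amputation) back into the
   covariates, where they raise subsequent mortality.

Applying deaths before transitions (and case fatality *with* the event
transition, where it belongs causally) is the standard cohort convention;
no half-cycle correction is applied by default, but
`econ$half_cycle_correction` and `econ$discount_from_cycle` expose the
alternatives.

### Risk equations

Transition probabilities come from per-equation specs in a columnar text
file (`risk_equations.csv`), config-overridable per equation. Four
functional forms are supported — constant rate, exponential
proportional-hazards (`p = 1 − exp(−exp(lp))`), Weibull proportional
hazards (cumulative-hazard increment over the current year of diabetes
duration), and logistic — with linear predictors
`lp = intercept + Σ β·(x − center)` centered at the baseline profile so
intercepts are interpretable as baseline (log-)hazards.

The published coefficient sets of the UKPDS Outcomes Model equations that
this design imitates are not reproducible here with citation-grade
fidelity, so the bundled defaults are this package's own: functional forms
and covariate choices follow the UKPDS tradition (positive HbA1c
coefficients on every glycemia-sensitive transition, SBP on renal and
macrovascular risk, lipids and smoking on MI/IHD, age on mortality), and
the intercepts were calibrated once to plausible annual event rates and a
plausible 30-year survival for a cohort aged 61 (background-mortality
hazard 1.4 % at age 61 doubling every ~8 years, plus history effects).
Consequently the engine reproduces the *structure and direction* of
published results for this comparison — dominance, lower complication
incidence under better glycemic control — not absolute published table
values, which depend on unpublished internals. Any user with a preferred
coefficient set can drop it in via `risk_equations_file` or inline
`risk_equations` overrides.

### Treatment switch

Both arms stay on their assigned regimen until start-of-cycle HbA1c exceeds
8.5 %, then switch to a shared basal-bolus intensification. HbA1c drifts
upward at `hba1c_drift_per_year` (default 0.1 %-points/yr — small but
nonzero, so both arms eventually intensify; exposed in the one-way
analysis). With the defaults the comparator (8.3 %) switches at cycle 3 and
IDegLira (7.6 %) at cycle 10: the intervention's advantage is seven extra
years of better glycemic control, fewer injections (1 vs 2 daily) and a
cheaper regimen-year. After the switch HbA1c is held at 8.5 % — the model
has one treatment line beyond intensification, so a second crossing is not
meaningful.

The shared post-switch strategy is itself a config object. Defaults chosen
once as realistic for basal-bolus: drug 20.5 CNY/day (basal 8.2 + bolus
12.3), 4 injections/day, non-severe hypoglycemia 0.5 and severe 0.05
events/patient-year. Pre-switch severe-hypoglycemia rates are 0 in both
arms: the trial-based rates (0.06/0.061) are labelled simply
"hypoglycemia" and the split is not published, so it is a user-tunable
field rather than a hidden assumption.

## Economics

* **Costs** (2022 CNY) follow the event/state convention: a one-off event
  cost in the year a complication occurs plus an annual state cost for
  every year in the state *including* the event year. Background treatment
  (3,349 CNY/yr) accrues on all alive mass. Treatment cost is daily price ×
  `days_per_year` = 365.25, which reproduces the published comparator
  annual total (47.3 CNY/day → 17,276 ≈ 17,277) to within printed
  rounding; the corresponding IDegLira total (37.6 × 365.25 = 13,733 vs a
  printed 13,702) differs by ~0.1 %, attributable to sub-0.1-CNY rounding
  of the printed daily components.
* **Utilities** combine strictly additively from a baseline of 0.936:
  state decrements (e.g. heart failure −0.186, ESRD −0.092), demographic
  progression (−0.024 per 10 years of age, −0.016 per 10 years duration,
  −0.006 per BMI unit above the anchor 35.9 — anchored at the comparator
  baseline so only between-arm BMI differences matter), injection burden
  (−0.00805 for 1/day, −0.0101 for 2/day; 3 and 4 injections extrapolate
  the published 1→2 step linearly), and per-event hypoglycemia
  disutilities (−0.014 / −0.047). The catalog defines decrements for one
  chain at a time; with parallel chains the floor at 0 is applied to the
  aggregate per-person expected utility, since no joint state exists.
* **Discounting**: both streams at 5 %/yr, divisor `(1+r)^t` with `t = 0`
  for the first cycle (first year undiscounted). The alternative
  `t = 1` start is a config flag.
* **Classification**: dominant iff ΔC < 0 and ΔQ > 0; dominated iff the
  reverse; equivalent iff both are zero; otherwise the ICER. NMB =
  85,698·ΔQ − ΔC by default.

## Uncertainty analysis

**One-way (tornado)**: discount rates float 0–8 %; every other selected
parameter (treatment prices, complication costs, utilities, efficacy
values, drift) floats ×0.9/×1.1, two full model runs per parameter. The
bar metric is incremental NMB: the base case is dominant, so a raw ICER is
undefined there and ICER bars would be ill-posed; ICERs are still reported
per bound where they exist. A bound that produces an invalid configuration
(e.g. baseline utility ×1.1 > 1) is recorded as a failed entry, never
silently dropped.

**PSA**: second-order Monte Carlo, 1000 draws by default. Families are the
conventional choices: beta for the baseline utility (method of moments on
mean 0.936, SE 0.120), gamma for costs, normal for utility decrements
(truncated at 0 on application: a decrement cannot be a gain) and for
treatment effects (SE = 95 % CI width / 3.92; the hypoglycemia rate ratio
is applied multiplicatively to the comparator rate and floored at 0).
Complication-cost SEs are not published; the default is 10 % of the mean,
stored as an explicit config field. Drug acquisition prices are
*administered* reimbursement/procurement prices, known with certainty, so
they are fixed in PSA and explored in the one-way analysis instead — this
choice was made a priori, not after inspecting PSA output. Parameters are
drawn independently (no correlation structure is published) in
sorted-parameter-path order from a single seeded generator, so adding a
parameter cannot silently reshuffle the draws of the others.

## Synthetic data and what a green test establishes

The test fixtures are generated in code:

* `make_toy_submodel()` builds 2–4-state chains with constant advance
  probability, whose occupancy has a *closed form* (a truncated binomial),
  giving an oracle that is independent of the engine. Engine-vs-oracle
  agreement is required to 1e-9 over 100 cycles.
* `perturb_config()` jitters every numeric parameter by ±10 % (seeded,
  clamped back to feasible ranges) to sweep conservation and monotonicity
  properties across the neighborhood of the reference parameterization.
* `emulate_parameter_catalog()` reproduces the statistical *shape* of the
  cost/utility catalogs (beta/gamma-feasible by construction) for
  distribution-fitting tests.

These fixtures validate the machinery — mass conservation, oracle
equivalence, moment recovery, dominance accounting — and the *direction*
of the headline result under the bundled defaults. They do not validate
the absolute calibration of the default risk equations against any
patient-level data; no test should be read as an epidemiological
validation of the coefficient file.

## Numerical choices

* Occupancy is propagated in exact arithmetic on small dense matrices;
  conservation is asserted at 1e-10.
* Competing exits from one state whose raw probabilities sum above 1 are
  proportionally renormalized with a warning (never silently truncated).
* Probabilities are clamped to [0, 1] after evaluation; equations with
  infinite rate (used by the `leave_prob = 1` toy) map to probability 1.
* Reported tables round relative risks to 2 decimals; raw ratios are kept
  as attributes. CSV output uses '.' decimals and no thousands separators.

## Known limitations

* The default risk-equation coefficients are calibrated, not estimated;
  absolute incidences and costs carry that uncertainty (the 30-year
  cumulative mortality of ~98.5 % remains on the high side of plausible).
* No patient-level heterogeneity: a mean-covariate cohort model understates
  nonlinear risk effects (Jensen gaps) relative to microsimulation.
* One treatment line beyond intensification; no re-switching, adherence or
  discontinuation.
* Chains are independent given covariates; comorbidity clustering beyond
  shared risk factors is not represented.
* Health-system perspective only: direct medical costs, no productivity or
  caregiver costs.
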