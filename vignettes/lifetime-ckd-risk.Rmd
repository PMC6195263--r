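---
title: "Simulating the lifetime risk of chronic kidney disease"
author: "ckdsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the lifetime risk of chronic kidney disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckdsim)
```

## The model

`ckdsim` is an individual-level microsimulation of chronic kidney disease
(CKD). Each simulated person is followed in annual cycles from their
baseline age until death or age 90, through eight states: no CKD, CKD
stages 1, 2, 3a, 3b, 4 and 5, and death. Stages follow the KDIGO
convention: stages 1 (eGFR ≥ 90) and 2 (60–89) additionally require kidney
damage, operationalised as persistent albuminuria (ACR ≥ 30 mg/g); stages
3a (45–59), 3b (30–44), 4 (15–29) and 5 (< 15) are defined by eGFR alone.
Staging is sequential in the GFR-defined range: a person reaching stage 4
must pass through 3a and 3b (when an annual step skips a band, the skipped
stages are recorded as attained), but a person who never develops
albuminuria can enter CKD directly at stage 3a.

The outcome of interest is the *lifetime risk* of CKD — the probability of
ever reaching any stage before death or age 90 — and the distribution of
the *highest stage attained*, contrasted across baseline BMI categories
(normal 18.5–24.9, overweight 25–29.9, obesity ≥ 30 kg/m²).

### Annual eGFR change

The engine's core is a linear model of the annual change in eGFR
(ml/min/1.73m² per year), estimated in a longitudinal CKD cohort
separately for persons with baseline eGFR < 60 and ≥ 60:

$$\Delta_i = \beta_0 + \beta_{\text{sex}} + \beta_{\text{race}} +
\beta_{\text{prot}} + \beta_{\text{dm}} + \beta_{\text{htn}} +
\beta_{\text{obesity}} + \varepsilon_i,\qquad
\varepsilon_i \sim N(0, \sigma^2_{\text{band}})$$

with the convention that positive values are annual *increases*. The
reference profile (male, non-Hispanic white, proteinuria < 0.1 g/24h, no
conditions, non-obese) has a base change of +0.42 (< 60 band) or +0.33
(≥ 60 band); risk factors contribute additive negative shifts, the largest
being heavy proteinuria (−4.17 / −4.56). The covariate part is
re-evaluated every cycle, so a person who develops diabetes picks up the
diabetes coefficient from the acquisition year onward. The person's
*baseline* eGFR band selects the parameter column for life, mirroring the
stratified estimation design; a person crossing 60 mid-course keeps their
baseline parameter set.

Two points deserve emphasis:

* **Variance interpretation.** The SD of the annual-change distribution
  (1.64 / 1.77) is taken from the *error term* of the mixed-effect
  estimation, i.e. a within-person residual. The engine therefore defaults
  to `slope_redraw_policy = "annual_iid"`: each year's change is a fresh
  normal draw around the covariate mean, so a person's cumulative decline
  is a random walk with covariate-determined drift. The alternative
  (`"once_at_baseline"`) treats the whole SD as a person-level random
  slope fixed at baseline. We examined both: carrying a draw from a
  distribution with SD 1.64 for life lets a sizeable fraction of young,
  otherwise-healthy people decline monotonically for five decades and
  produces lifetime stage-5 risks near 5%, an order of magnitude above the
  published 0.3–0.6%; the iid reading reproduces the published
  magnitudes. The true split of the total variance into between- and
  within-person components is not public, so the policy is a configuration
  switch with `annual_iid` as the default.
* **Variance calibration.** The ≥ 60 estimation sample was small and
  unrepresentative, over-stating decline variability for that group. The
  model therefore deflates the ≥ 60 *variance* by a multiplier
  (`variance_multiplier_ge60`); the SD is multiplied by its square root.
  The calibrated value used originally is unpublished. **The shipped
  default of 0.5 is an unanchored placeholder** — treat it as
  configuration, not as an estimate.

eGFR is floored at 1.0 ml/min/1.73m² to keep values physical; stage 5 is
absorbing for staging purposes (the highest-stage ratchet never
decreases) while the simulation itself continues to death or age 90.

### Obesity, comorbidities and mortality

Overweight and obesity act on CKD *indirectly*, by multiplying the annual
background incidence of diabetes (RR 1.85 men / 1.36 women for obesity),
hypertension (2.23 / 2.63 for obesity, 1.48 / 1.70 for overweight) and
coronary heart disease (1.58 / 1.43, sex-invariant), and *directly*
through the obesity coefficient of the eGFR model (+0.26 / −0.15 by
band). Relative risks of exactly 1 (diabetes/overweight, MI, stroke) are
stored explicitly so that sensitivity scaling treats every parameter
uniformly. RRs multiply annual probabilities with a cap at 1 — exact for
small probabilities, a documented approximation to hazard-scale scaling.

BMI itself drifts annually by age band, race group and sex (e.g. +0.23
kg/m²/yr for white men aged 30–49, +0.020 for black men 50+). Drift
estimates exist only for white and black populations; Hispanic and other
groups map onto the white coefficients by default (configurable). A
normal-weight 35-year-old therefore typically becomes overweight in
mid-life, which compresses the contrast between baseline BMI groups at
young ages — visible in the results as a larger obesity effect in the
50–64 baseline band than the 30–49 band.

Albuminuria progresses in one-step annual transitions, normal → moderate
→ severe. Incident (normal → moderate) albuminuria follows an age table
multiplied by 2.5 for prevalent diabetes and 1.5 for prevalent
hypertension: diabetic and hypertensive nephropathy are the dominant
causes of incident proteinuria, and without these multipliers the model
cannot carry the obesity effect through its diabetes/hypertension pathway
— which the underlying literature identifies as the dominant mechanism.
The proteinuria covariate of the slope model is the categorical image of
albuminuria (normal → < 0.1 g/24h, moderate → 0.10–0.49, severe →
0.50–1.49, with a configurable fraction of severe cases assigned to
≥ 1.50); it never downgrades.

Mortality is an annual draw from an all-cause life table (age × sex),
multiplied by a hazard ratio for the current CKD stage and, if any of
CHD, stroke or MI is present, a CVD hazard ratio. There is deliberately
**no direct BMI term in mortality**: controlled estimates find no effect
of obesity on non-CVD mortality, so BMI influences survival only through
the conditions it causes. This equality is a tested contract.

The within-cycle update order is fixed: mortality → BMI drift → incident
events → eGFR step → staging → age increment. The original ordering is
unpublished and the choice moves results slightly, so it is a single
global convention rather than a configuration knob.

### The synthetic cohort

The original analysis drew its baseline cohort from national survey
microdata (NHANES 1999–2010), which is not redistributable. The
`cohort_spec()` / `generate_cohort()` pair instead generates a synthetic
US-adult-like population: configurable marginals for age band (45/32/23%
over 30–49 / 50–64 / 65–90), sex (52% female), race/ethnicity, BMI
category by age band (roughly one-third obesity), a linear-in-age eGFR
model (mean 103 at age 30, −0.7 per year of age, SD 12.5, truncated to
(5, 150]), and prevalence tables for diabetes, hypertension, CVD and
albuminuria by age band and BMI category. Every cohort also carries a
serum creatinine column obtained by inverting the 2009 CKD-EPI equation,
so both baseline input paths (eGFR directly, or creatinine through
`ckd_epi_egfr()`) are exercised. Because surveys observe albuminuria
once while staging requires persistence, moderately increased albuminuria
is retained with probability 0.6 (configurable) and otherwise reset — a
probabilistic stand-in for the published persistence-adjustment
algorithm, whose exact form is not public.

**What the generator does and does not emulate.** Marginals and their
age/BMI gradients are plausible for US adults; the *joint* structure is
conditionally independent given age band and BMI category, the eGFR-age
relation is linear with homoscedastic noise, and the low-eGFR /
albuminuric tail is thinner than in real survey data. Passing tests
therefore demonstrate that the simulation machinery is correct and that
the obesity contrast has the published direction and approximate
magnitude under a realistic synthetic population — not that the package
reproduces survey-based estimates. In particular, the lifetime risk of
reaching stage 4 as the highest stage runs ~1 percentage point below the
published central estimates: deep-stage attainment depends on the heavy
baseline tail of the real cohort and on unpublished background rate
tables, both of which are stand-ins here (see the package README for the
acceptance-run numbers).

## Parameters that matter

| Parameter | Default | Units | Why it matters |
|---|---|---|---|
| `base_change`, coefficients | published values | ml/min/1.73m²/yr | drift of every trajectory |
| `sd_annual_change` | 1.64 / 1.77 | ml/min/1.73m²/yr | tail mass reaching deep stages |
| `variance_multiplier_ge60` | 0.5 (placeholder) | — | deflates ≥ 60-band variance |
| `slope_redraw_policy` | `annual_iid` | — | random walk vs fixed slope; see above |
| albuminuria retention | 0.6 | probability | baseline stage-1/2 prevalence |
| `alb_mult_diabetes` / `_hypertension` | 2.5 / 1.5 | — | strength of the indirect obesity pathway |
| `hr_mortality_by_stage` | 1…3 (placeholder) | hazard ratio | competing risk truncating deep stages |
| `bootstrap_reps` | 100 | count | CI resolution (percentile rule) |

Background incidence and mortality tables (5-year age bands × sex) ship as
synthetic, non-authoritative stand-ins shaped like contemporary US
epidemiology: Gompertz-style mortality (doubling roughly every 8 years of
age), incidence ramps that rise to a plateau in late middle age.
Validation requires every series to be non-decreasing in age.

## Numerical conventions

* **Reproducibility.** Every person consumes random numbers only from a
  private stream seeded by a deterministic integer hash of
  `(master_seed, person id)`, kept below 2³¹. Results for a given id are
  therefore bit-identical under cohort permutation or subsetting, and the
  whole pipeline is reproducible from `(cohort spec, seeds)`.
* **Bootstrap.** "Simulating the lifetime risk 100 times" is read as 100
  bootstrap replicates that resample persons with replacement *and* use
  fresh simulation randomness per replicate, so both sources of
  uncertainty propagate (config switch `bootstrap_fresh_sim = FALSE`
  gives resampling-only). CI bounds are the 2.5/97.5 percentiles with
  linear interpolation between order statistics (type-7); with B = 100
  the percentile definition is not innocuous, hence fixed. Percentile
  intervals do not guarantee containment of the point estimate; violations
  are flagged, never adjusted.
* **Group comparison.** The p-value for a between-group difference is a
  normal approximation on paired replicate differences,
  `2Φ(−|d̄|/SE_boot)` — a declared convention; the original test is
  unspecified.
* **Degenerate inputs.** eGFR is floored at 1; probabilities are capped
  at 1; empty grouping cells are reported as missing, not zero; exact
  threshold landings (eGFR exactly 45, say) remain in the band *above*
  for that year, so a constant slope s from eGFR₀ first attains the
  stage below threshold τ at cycle ⌊(eGFR₀ − τ)/|s|⌋ + 1.

## Problem sizes

The packaged test-suite sizes are the package's own choices: analytic
first-passage checks on a 20-trajectory fixture; slope-model recovery on
200,000 draws; the BMI-exchangeability contract on a 50,000-person
seed-matched pair; headline reproduction on n = 10,000 per baseline BMI
group; the bootstrap exercised with B = 100 on 1,600 persons; and the six
±25% one-way sensitivity analyses (RR of diabetes for obesity, RR of
hypertension for obesity, obesity eGFR coefficient) on 5,000 persons per
group with matched seeds. The acceptance script
(`scripts/acceptance.R`) recomputes the headline quantities at n = 10,000
per group.

## Known limitations

* All background rate tables, cohort marginals and stage/CVD mortality
  hazard ratios are synthetic stand-ins; absolute risk levels inherit
  their uncertainty. The relative ordering across BMI groups is far more
  robust than any absolute number.
* No acute kidney injury, measurement error in eGFR, treatment effects,
  smoking, remission, or secular trends; stage 5 has no treatment
  modalities (dialysis/transplant) within it.
* The within-person iid variance reading likely *understates*
  between-person persistence somewhat, and the synthetic baseline lacks
  the heavy low-eGFR tail of survey data; both depress deep-stage (4–5)
  lifetime risks relative to the published central estimates, which is
  visible in the acceptance results for the stage-4 buckets.
* Annual cycles with no half-cycle correction; ages advance in integer
  years; the start year (2010) is bookkeeping only.
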