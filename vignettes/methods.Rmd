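---
title: "Model structure, calibration and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, calibration and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyrocea)
```

`thyrocea` implements a two-strategy, six-state annual-cycle Markov cohort
model of ultrasound screening versus non-screening for thyroid cancer in
asymptomatic adults. This vignette explains the model, the conventions the
published summary tables leave open and how we resolved them, the numerical
choices, and what the bundled synthetic inputs do and do not represent.

## The cohort model

A closed cohort enters at age 20 entirely in the `health` state and is
propagated over 55 one-year cycles. Each cycle the occupancy vector is
multiplied by an age-dependent transition matrix built from five annual
probabilities per strategy — nodule incidence (`health → btn`), cancer
incidence (`health → mtn`), malignant progression of a benign nodule
(`btn → mtn`), excess cancer mortality (`mtn → death`), and post-operative
recurrence (`postop → recurrence`) — plus background mortality `q(age)`
applied to every living state. Progression and recurrence are identical
across strategies (same surgery, same tumor biology); the incidences and
excess mortality differ because screening detects more disease.
`recurrence` is absorbing for disease transitions but still subject to
background mortality, so the cohort can go extinct; `death` is fully
absorbing.

Quality-adjusted life years multiply each state's occupancy by its utility
(health 1.00, benign nodules 0.99, detected cancer 0.60, post-operative
stability 0.99, recurrence 0.54, death 0). Costs and QALYs are discounted at
5% per year; cycle 0 is undiscounted and cycle *k* is weighted by
$(1+r)^{-k}$, with rewards evaluated on start-of-cycle occupancy. No
half-cycle correction is applied by default. Both conventions are switches
(`discount_cycle_offset`, `half_cycle_correction`) because published
decision-tree software defaults vary and the source tables do not pin them
down.

Multi-year cumulative probabilities are converted to annual ones with
$p = 1-(1-p_t)^{1/t}$ (`annualize_probability()`); the bundled transition
probabilities are taken as already annual.

## Resolving what the summary tables leave open

The published parameter tables give cost components only as abbreviations
and never state which health states incur them. The mapping is therefore
configurable (`analysis_settings()`), and the default configuration is the
one under which the model reproduces the published base case. It charges:

* the examination cost — ultrasound (`c_n`, \$251.46/cycle) in the screening
  arm, routine physical (`c_o`, \$50.16/cycle) otherwise — to **everyone
  alive**, every cycle (lifelong annual screening);
* benign-nodule follow-up (`c_nf`, \$798.60/cycle) to **benign-nodule
  occupancy**;
* the one-time treatment cost (`c_t`, \$20,174.58) to the cohort mass
  **entering** the cancer state each cycle, not to prevalent occupancy;
* recurrence care (`c_recurrence`, \$6,050.22/cycle) to recurrence
  occupancy;
* post-cancer surveillance (`c_tf`, \$1,264.90/cycle) to post-operative
  occupancy **in the screening arm only**. We read `c_tf` as the
  imaging-based surveillance package of the screening programme; in the
  non-screening arm, follow-up of treated patients happens through the
  routine annual examination that every living member of that arm is
  already charged. This asymmetry is the single mapping choice needed to
  land the non-screening total near its published value, and it is a
  switch (`tf_arms = "both"` restores the symmetric reading).

A second structural choice concerns residence in the detected-cancer state.
Thyroid surgery involves one to two days in hospital and about two weeks of
recovery — a small fraction of a one-year cycle — so by default detection
and surgery are resolved **within** the detection cycle (`mtn_instant`):
survivors occupy `postop` at cycle end and the cancer state has zero
residence time (its utility never accrues). The alternative, a full
one-cycle stay at utility 0.60, is available via `mtn_instant = FALSE`; it
lowers the base-case ICER by roughly 30% and moves it well away from the
published value, which is why the within-cycle convention is the default.
Either way the transition *matrix* keeps the full six-state structure
(`build_transition_matrix()`), with the cancer row sending excess mortality
plus `q(age)` to death and the remainder to post-operative stability.

## Background mortality

The published analysis used national life tables whose values it does not
reproduce. The bundled substitute is a synthetic Gompertz–Makeham table
(`synthetic_life_table()`, and it is labelled synthetic in the bundled
config): hazard $\mu(x) = A + B e^{\theta x}$ with accident floor
$A = 6\times10^{-4}$ (young-adult mortality of a high-income population,
$q(20) \approx 7.5\times10^{-4}$), slope $\theta = 0.095$ (mortality doubling
roughly every 7 years), and $B$ calibrated by root finding so period life
expectancy at birth is 80 years. Ages beyond the last row reuse the last
hazard. Users can substitute any real life table as a two-column CSV
(`read_life_table()`).

With this table and the default mapping the base case evaluates to

```{r base, eval = FALSE}
compare_strategies(thyroid_screening_spec())
# screening      $19,651.35   18.8914 QALY
# non-screening  $16,215.32   18.8591 QALY
# ICER $106,513/QALY -> non-screening at $50,000/QALY
```

within 5% of the published totals, 0.16 QALYs of the published
effectiveness, and 0.5% of the published ICER.

## Parameter uncertainty

Probabilities and utilities carry beta distributions and costs gamma
distributions, using the printed shape parameters as-is wherever they are
usable. Gamma shapes are interpreted as shape/scale, so means reproduce the
printed bases only approximately (the treatment-cost mean is 1.5% above its
base; two follow-up costs are 12–17% above). We deliberately do not
recalibrate them: the printed shapes are the stated uncertainty model, and
centering them would also have shifted the acceptability curve.

One printed utility distribution (post-operative stability, "Beta(1, 0)") is
unusable. It is repaired by moment matching: a beta with mean equal to the
base value 0.99 and standard deviation chosen as the largest value whose
symmetric two-standard-deviation interval fits inside both the printed range
(0.74–1.00) and the unit interval — here 0.005. A flat quarter-range rule
(sd 0.065) would place the two-sigma interval outside the support and
produce a J-shaped distribution with median at 1, which badly misstates the
uncertainty of a mean-0.99 utility and, empirically, inflates the
acceptability crossover by about \$15,000. For a base centred in its range
the feasibility-constrained rule reduces exactly to the quarter-range rule.

The PSA (`run_psa()`) draws every uncertain parameter independently, in
declaration order, from one seeded generator; strategy-shared parameters are
drawn once per draw and applied to both arms, and each draw evaluates both
strategies with the same sampled set. Draws whose competing probabilities
exceed row feasibility are redrawn and counted. The one-way analysis
(`tornado()`) varies each table row across its printed range (base ±10%
where no range exists, and the garbled recurrence-cost upper bound repaired
as 1.5× base), with strategy-shared rows varied in both arms together; its
primary metric is the incremental net monetary benefit at the threshold,
which remains defined through dominance regions.

## Numerical choices

* Transition rows are validated to sum to one within $10^{-12}$ and the
  trace to conserve cohort mass within $10^{-10}$.
* The engine is validated against closed-form geometric toys to $10^{-9}$
  and against an individual-level microsimulation (`microsim_oracle()`)
  within three standard errors.
* NMB ties in the acceptability computation go to the cheaper strategy, and
  with equal costs to the more effective one — measure-zero events fixed for
  determinism.
* The acceptability grid spans \$0–200,000/QALY in \$5,000 steps, covering
  both the \$50,000 threshold and the observed crossover.
* Currency is carried at full precision and only rounded for display.

## Problem sizes used in the checks

The bundled checks run the 1,000-draw PSA over ten seeds (the scale at which
the acceptability probability stabilizes to within a point or two),
microsimulations of 1.5–2 × 10^5 individuals, and property sweeps over 100
seeded random specifications from `generate_random_model()`.

## What the synthetic inputs do and do not show

The random-scenario generator produces structurally valid models across wide
parameter ranges; passing its sweeps demonstrates conservation, feasibility
and engine/oracle agreement, not clinical realism. The synthetic life table
reproduces the *level* of longevity (life expectancy 80) with a smooth
parametric hazard; it does not reproduce the age-specific quirks of any real
national table, and base-case QALY totals inherit a corresponding
uncertainty of a few tenths. The nodule-incidence probabilities are taken
as printed even where surprising (palpation-era incidence of 0.68/year
exceeds the ultrasound-era 0.19/year); the model propagates, and cannot
correct, its sources.

## Known limitations

Two alternatives only; no nodule-size or cancer-stage granularity; no
regression of benign nodules; no post-operative-complication costs; no
correlation structure in the PSA; costs as printed with no inflation
adjustment. These mirror the scope of the analysis the package reimplements.
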