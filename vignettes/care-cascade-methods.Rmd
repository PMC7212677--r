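---
title: "Methods: care-cascade projection, costing, and screening optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: care-cascade projection, costing, and screening optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carecascade)
```

# The problem

A regional type 2 diabetes programme loses patients at every stage of the
care continuum: people are never screened, screen positive but are never
confirmed, are diagnosed but never linked to care, or are in care but never
attain sustained glucose control (HbA1c at or below 7.0%). `carecascade`
provides the quantitative machinery to analyse such a cascade for a
Poltava-like oblast of ~1.4 million inhabitants: where the breakpoints are,
what each service line costs, how to split screening effort between
facilities and community outreach, and what an investment in treatment
adherence buys back in reduced monitoring costs.

# The compartmental cascade model

## Model and update scheme

The population with (or at risk of progression through) type 2 diabetes is
divided into mutually exclusive compartments: unscreened prevalent cases,
screened-positive, confirmed, linked to care, then on treatment in one of
three groups (non-pharmacological, oral, insulin), each split into a
glucose-controlled compartment and an uncontrolled sibling, plus an explicit
death sink. Each arrow carries an annual per-person transition probability.

The update is a discrete-time forward-Euler step: over a step of `dt` years,
every flow moves `count * rate * dt` people, all flows evaluated
simultaneously from the pre-step state. Incident cases enter the unscreened
compartment at `annual_incident_cases * dt`; background mortality (plus any
per-compartment excess) routes people to the death sink, so the grand total
is conserved exactly up to incidence — a property asserted to 1e-9 in the
tests. A step in which any compartment's scaled outflow would exceed 1 is
refused with an error rather than silently producing negative counts.

Rates are annual probabilities scaled linearly by `dt`. This keeps
programme-level coverage fractions directly usable as inputs, at the price
of first-order discretization error; on two- and three-compartment models
the projection is verified against exact closed forms (`(1 - r dt)^(1/dt)`)
and an independently coded matrix-power solution.

## Coverage drives flow

Increasing the coverage of an intervention (screening, say) increases the
rate of the flow it drives. The link is deliberately the simplest one
consistent with that direction: `effective_rate()` scales the base rate by
`coverage / reference_coverage` and clips to [0, 1]. A logistic or other
saturating link would be equally defensible; the linear choice is documented
here precisely because the underlying tool this emulates does not publish
its link function.

## Choice of the default time step

The natural default `dt = 0.25` (quarterly) was tried first, but on the
default synthetic region halving it changes some fast-flowing compartment
counts at a four-year horizon by 2.7% — more numerical drift than we accept.
At `dt = 0.05` (about 18 days) the same halving experiment moves no
compartment by more than 0.5%, and a four-year projection of an
11-compartment region still takes milliseconds, so **0.05 is the package
default**. The convergence experiment is part of the test suite, so a model
whose rates make the default step too coarse will fail loudly.

# Bottom-up costing and the spending ledger

Unit costs are assembled from ingredients: drug consumables (+7% VAT),
other consumables (+20% VAT), staff minutes at an average professional
salary rate, and overheads, converted from hryvnia to USD at the fixed
mid-2018 rate of 26.3138 UAH/USD (`build_unit_cost()`). Spend on a service
line is unit cost times people covered.

The published regional ledger prints unit costs rounded to two decimals but
spends computed from unrounded values, so a recomputed spend differs from
the printed one by up to a few tenths of a percent. `recompute_ledger()`
therefore treats the two-decimal unit costs and the people counts as
canonical, recomputes spends from them, and flags lines whose printed spend
deviates by more than 1.5% — wide enough for display rounding, tight enough
to catch genuine transcription errors.

Derived people counts round half away from zero (`round_half_up()`): that
convention reproduces the published treatment-mix accounting exactly
(8,600 insulin patients of whom one third, 2,867, also take oral drugs;
8% of 40,000 = 3,200 non-pharmacological; 28,200 oral-only; 31,067 eligible
for the oral co-payment scheme).

One published inconsistency is preserved rather than papered over: the
abstract describes monitoring for uncontrolled non-pharmacological patients
as "10%" dearer, while the cost table's 28.28 vs 24.48 USD is 15.5% dearer.
The package reports the computed 15.5%.

# Saturating cost-coverage curves

Outreach screening gets more expensive per person as coverage rises — the
easily reached are reached first. The curve family is parameterized by the
unit cost `u` at the low-coverage limit and the maximal attainable coverage
(saturation) `sigma`, with an eligible-population denominator `N`:

$$\mathrm{coverage}(s) \;=\; \sigma \,\tanh\!\Big(\frac{s}{\sigma N u}\Big),$$

which is the logistic form `sigma * (2/(1 + e^{-2x}) - 1)` written
compactly. It satisfies all the contract limits: coverage 0 at spend 0,
marginal cost exactly `u` at the origin, strictly increasing and concave,
asymptoting to `sigma`, with the exact inverse
`spend = sigma * N * u * atanh(c / sigma)`. Facility screening is costed
linearly (constant 0.66 USD per test): the saturating form is applied to the
outreach modality only.

**The denominator is a modelling choice.** Two conventions circulate:
coverage as a fraction of the whole adult population, or of the undiagnosed
prevalent pool. The package default is the **adult population** (1.4 m);
the other convention is a one-argument change (`eligible_population` in
`cost_curve()`). Results should state which was used. Note that under the
default convention, screening volumes sized for ~5,000 new cases a year
imply outreach coverage far below saturation, so the cost surface is nearly
linear there and optimal outreach shares tend to sit at the ends of the
share range; a steeper (small-denominator) curve produces interior optima.

# The screening-mix optimizer

For a target of 5,000 newly identified cases per year (~33% above estimated
annual incidence, i.e. actually closing the diagnosis gap), the optimizer
asks: what fraction of all screening events should be outreach? Facility
positivity defaults to the observed 3,350/41,833 ≈ 8.0%; outreach positivity
(8–16%) and saturation (10–20%) are swept as scenario axes because both are
genuinely unknown — outreach campaigns attract re-testers who dilute the
unique-case yield, so positivity is treated as net of re-testers.

The optimization is an exhaustive grid search over the outreach share
(default 101 points): it is one-dimensional, costs milliseconds, cannot get
trapped in local minima, and mirrors the heatmap presentation of the
results. Shares whose implied outreach coverage would reach saturation are
infeasible and excluded; ties break toward the smaller share. The tests
require exact agreement with an independent brute-force enumeration, the
qualitative orderings (optimal share non-decreasing, minimal cost per case
non-increasing, in both positivity and saturation), and the linear lower
bound `0.66 / positivity` on every cost per case.

The target counts positive screens; if only confirmed diagnoses should
count, divide the target by the confirmation rate before calling the
optimizer.

# Glucose-control investment arithmetic

Three linked calculations quantify the case for investing in adherence:

* **Co-payment offset.** Monitoring an oral-treatment patient costs
  27.24 USD/yr less once they attain control; against an annual oral-drug
  co-payment of 34.30 USD the state recoups 79.4%, presented as 80%
  (rounding to the nearest ten percent is a deliberate presentation layer,
  kept separate from the raw value).
* **Savings per control point.** If one more percentage point of the
  40,000 in care attain control (400 patients), apportioned across
  treatment groups by the overall mix (3,200/28,200/8,600), the monitoring
  saving is 400 × (0.08·3.80 + 0.705·27.24 + 0.215·29.88) = 10,372.96 →
  10,373 USD/yr. Apportioning by the uncontrolled mix instead gives 10,406;
  both conventions are implemented, the mix-proportional one is the default
  because it is the one the published accounting uses. Savings are linear
  in the shift size.
* **Counselling scale-up.** Reinvesting those savings into enhanced
  adherence counselling (current spend 2,085 USD/yr reaching 3,509 people)
  funds a (2,085 + 10,373)/2,085 = 5.98 ≈ 6-fold expansion — about 21,000
  people, roughly half of those in care. The "additional funds on top of
  the existing budget" reading is adopted because it is the only one that
  yields a six-fold figure.

# The synthetic-data generator

`region_spec()` / `generate_region()` produce a Poltava-like region:
1.4 m adults, 60,000 prevalent cases (~4.3% prevalence), two-thirds
diagnosed, 40,000 in care with the 8% / 70.5% / 21.5% treatment mix and
30% / 30% / 23% controlled fractions — numbers that reproduce the published
six-cell monitoring table exactly. Prevalence, incidence (3,750/yr),
mortality (1.5%/yr background, +1%/yr for uncontrolled compartments) and
the transition rates are **assumptions** collected in `region_defaults()`,
standing in for an unpublished supplementary table; they were chosen once
to be consistent with the observed 2016 flows (≈3,650 confirmations out of
≈20,000 undiagnosed gives a screening rate near 0.2/yr) and with ~25–30%
controlled at equilibrium, and are not tuned further.

Counts are derived deterministically from fractions by rounding; a
stochastic mode draws the within-care splits multinomially for property
tests. `simulate_screens()` adds an event-level stream with known true
positivity and a re-tester fraction (a positive screen is a *new* case only
with probability 1 − re-tester fraction); `recover_positivity()` estimates
the new-case positivity with an exact binomial interval, and the test suite
checks 95% interval coverage within [93%, 97%] over 500 seeded streams.

What a green test does **not** establish: the generator makes no attempt to
match the real region's register statistically — no age or sex structure,
no geography, no secular trends in incidence, no correlation between
treatment group and screening behaviour. Green tests establish the
*arithmetic and the contracts*, not epidemiological realism.

# Numerical choices and degenerate inputs

* Conservation is checked to 1e-9 relative per step; tiny negative counts
  from floating-point cancellation (>-1e-9) are clamped to zero, anything
  larger is an error.
* `spend_from_coverage()` refuses coverage at or beyond saturation
  (`atanh` would diverge); the optimizer treats such shares as infeasible
  rather than erroring.
* A zero reference coverage, a zero co-payment, a zero controlled unit
  cost, and an empty screening stream are all explicit errors, not NaNs.
* Ties in the share grid break toward the smaller share, so "do less
  outreach" wins when outreach buys nothing.

# Known limitations

Uncertainty is not propagated (point projections only); there is no
age/sex structure, no type 1 diabetes, no complication costing, no
economies of scale in unit costs, and no behavioural model of *how*
co-payments or counselling change adherence — the investment arithmetic
assumes the adherence-to-control link and prices its consequences.

# A worked run

```{r}
mix <- derive_treatment_mix(40000, 8600, 1 / 3, 0.08)
mix

t <- poltava_monitoring_table()
monitoring_cost_gap(t, "oral")
savings_per_control_point(t)$savings_presented
counselling_scaleup(2085, 10373, 3509)$fold_presented

reg <- generate_region(region_spec(seed = 1))
model <- default_cascade_model(region_spec(seed = 1))
traj <- cascade_project(reg$state, model, end_year = 2020)
tail(as.data.frame(traj), 1)

sweep_screening_grid(5000)
```
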