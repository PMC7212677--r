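# carecascade

Decision-support analytics for regional type 2 diabetes programmes: where
the care continuum leaks, what each service costs, how to split screening
between clinics and community outreach, and what investing in treatment
adherence buys back. Written for health economists and programme analysts
working with cascade data of the kind an oblast-level health department
holds — compartment counts, unit costs, coverage figures — rather than
patient-level records.

## What it computes

**Cascade projection.** The population moves through compartments
(unscreened → screened → confirmed → linked to care → on treatment
{non-pharmacological, oral, insulin} → glucose-controlled or not, plus a
death sink) with annual transition probabilities. The update is
forward-Euler with simultaneous flows: over a step *dt*,

> flow(source → target) = *n*(source) · *r* · *dt*,

with incidence entering the unscreened pool and deaths routed to the sink,
so people are conserved exactly. Coverage of an intervention scales the
rate of the flow it drives: *r*<sub>eff</sub> = *r* · *c*/*c*₀, clipped to
[0, 1].

**Costing ledger.** Bottom-up unit costs (consumables with 7% VAT on drugs
and 20% otherwise, staff minutes, overheads, converted at 26.3138 UAH/USD),
spend = unit cost × people, and an auditor that recomputes every ledger
line and flags inconsistencies beyond display-rounding tolerance.

**Screening economics.** Outreach screening follows a saturating
cost-coverage curve with unit cost *u*, saturation *σ* and eligible
population *N*:

> coverage(*s*) = *σ* · tanh(*s* / (*σNu*)),  spend(*c*) = *σNu* · atanh(*c*/*σ*),

so the marginal cost starts at *u* and diverges as coverage approaches
*σ*. Facility screening is linear at 0.66 USD/test. A grid optimizer finds
the outreach share of screening events minimizing the cost per newly
identified case for a 5,000-case target, swept over outreach positivity
(8–16%) and saturation (10–20%).

**Glucose-control investment arithmetic.** Monitoring an uncontrolled
patient costs more than monitoring a controlled one; the package turns
those gaps into the co-payment offset, the savings per percentage point of
control improvement, and the affordable scale-up of adherence counselling.

## Worked example

```r
library(carecascade)

derive_treatment_mix(40000, 8600, 1/3, 0.08)
#> <treatment_mix> 40,000 in care
#>   non-pharma 3,200 | oral-only 28,200 | insulin 8,600 (2,867 also oral)
#>   eligible for oral co-payment scheme: 31,067
```

Of 40,000 people in care, 8,600 receive insulin (one third of whom also
take oral drugs) and 8% are managed non-pharmacologically; the remaining
28,200 are oral-only, making 31,067 patients eligible for the oral-drug
co-payment scheme.

```r
t <- poltava_monitoring_table()
monitoring_cost_gap(t, "oral")
#> $difference_usd
#> [1] 27.24
#> $ratio
#> [1] 2.063647

savings_per_control_point(t)$savings_presented
#> [1] 10373
copayment_offset(27.24, 34.30)$offset_presented
#> [1] 0.8
```

Monitoring an uncontrolled oral-treatment patient costs 27.24 USD/yr more
than a controlled one — about twice as much. One percentage point more of
the in-care population attaining control saves 10,373 USD/yr in monitoring,
and the oral gap alone covers 80% of the 34.30 USD annual co-payment.

```r
sweep_screening_grid(5000)
#> <screening_mix_grid> target 5,000 new cases; 9 positivity x 6 saturation levels
#>   cheapest corner: 4.14 USD/case at positivity 16%, saturation 20% (share 100%)
#>   dearest corner:  8.24 USD/case at positivity 8%, saturation 10% (share 0%)
```

Cost per newly identified case falls, and the optimal outreach share rises,
as outreach campaigns become better targeted (higher positivity) and more
scalable (higher saturation). Note the absolute optima depend on the
cost-curve denominator convention — see the methods vignette.

```r
reg <- generate_region(region_spec(seed = 1))
model <- default_cascade_model(region_spec(seed = 1))
cascade_project(reg$state, model, end_year = 2020)
```

projects the synthetic region's cascade from 2016 to 2020 under constant
coverage (by 2020, ~18,500 prevalent cases remain unscreened and ~9,300 of
the ~40,600 treated patients are glucose-controlled).

## Layout

- `R/` — cascade model, costing, cost curves, optimizer, adherence
  arithmetic, synthetic data, CSV/JSON IO
- `vignettes/care-cascade-methods.Rmd` — the model, assumptions, parameter
  defaults and their rationale, limitations
- `inst/cli/carecascade.R` — thin command-line wrapper
  (`project`, `ledger`, `curves`, `optimize-screening`, `adherence`, `synth`)
- `tests/testthat/` — unit, property and end-to-end tests
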