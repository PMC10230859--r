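---
title: "Modelling pooled funding for neglected-disease trials: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pooled funding for neglected-disease trials: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prndsim)
```

# The model

`prndsim` evaluates a hypothetical pooled-funding mechanism that pays for
late-stage (phase III) clinical trials of poverty-related and neglected
disease (PRND) products. Three design options differ in scope: option 1
funds vaccines for four diseases (HIV, TB, malaria, pneumococcal
pneumonia); option 2 adds therapeutics and five neglected tropical
diseases; option 3 covers vaccines, therapeutics and diagnostics for the
full PRND list. The evaluation chains three sub-models.

## Pipeline simulation

Every product candidate is an independent entity characterised by an
*archetype* — a product class crossed with a development-complexity level
(e.g. `vaccine-complex`, `dx-assay`) — that fixes its cost (2020 USD
millions), duration (years) and probability of success for each of the
four trial stages. Trial stages are servers with infinite capacity, so
candidates never queue and the simulation factorises over candidates: each
candidate sits in a stage for its full duration, then draws a Bernoulli
success; failures exit, successes advance. A **launch** is a successful
exit from the final stage inside the 2019–2030 window; the product reaches
the global market one calendar year later. Candidates already in phase III
in 2019 are excluded at portfolio construction (their trials are assumed
funded). For the first five years, ten new candidates per archetype enter
the earliest stage annually (*replenishment*). Results are averaged over
100 Monte Carlo runs.

Numerical conventions that matter:

* **Missing stages.** A stage with no cost, duration *or* success
  probability is skipped outright (repurposed drugs start at phase II; a
  diagnostic assay "launches" on exiting phase II). Within a stage that
  has *some* parameters, a missing duration counts as 0 years, a missing
  cost as 0, and a missing success probability as certain success — this
  reproduces the one genuinely odd archetype (diagnostic platform
  development: a phase III with a stated length but no cost and no
  attrition) without special-casing it.
* **Cost booking.** Phase III costs are sunk at stage *entry* — a failed
  trial still costs its full amount — and are spread uniformly over the
  calendar years the stage spans so they can be discounted. Undiscounted
  totals therefore satisfy, exactly: total phase III spend = entrants x
  per-archetype phase III cost.
* **Seeds.** Run *r* of a Monte Carlo batch uses `base_seed + r - 1`, so
  any single run can be reproduced in isolation. In `run_scenario()` the
  master seed `s` derives the portfolio seed (`s`), epi-table seed
  (`s + 1`) and Monte Carlo base seed (`s + 100`).
* **Monotonicity by construction.** A candidate's success draws are
  consumed in a fixed order and the walk is never truncated at the
  horizon, so under a shared seed, inflating durations can only delay or
  drop launches — never create them. The duration-sensitivity test
  exploits this to check monotonicity exactly per seed instead of
  statistically.

## Benefits

On market entry, a vaccine removes 10 percentage points of *base-case*
incidence per year, capped at a 90% reduction; a therapeutic or diagnostic
raises treatment coverage by 10 points per year to a 90% ceiling (baseline
coverage above 90% is left untouched). Both ramps are **additive in
percentage points**, not compounding: only the additive reading reaches
exactly the stated 90% maximum (in ramp year 9). Benefits accrue from
market entry through 2035. Base-case incidence and coverage are held
constant at their input values — no secular trend is imposed.

From the base-case vs with-product trajectories the model computes, per
disease-year: cases averted (incidence difference), deaths averted
(treated/untreated case-fatality rates applied to treated/untreated case
volumes), YLL averted (deaths averted x death-weighted residual life
expectancy), YLD averted (disability weight x illness duration of treated
and untreated cases), DALYs averted (YLL + YLD, exactly additive), and
treatment costs averted. Two structural choices:

* **First-launch attribution.** Only the first vaccine launch per disease
  starts the incidence ramp, and only the earliest
  therapeutic-or-diagnostic launch starts the (single, shared) coverage
  ramp. Later launches of the same class for the same disease add nothing.
  This bounds the benefit overestimate that aggressive replenishment could
  otherwise produce.
* **Treatment costs averted can be negative.** The cost equation credits
  avoided cases but debits the *extra* cases treated when coverage
  expands. A coverage-only launch therefore has strictly negative
  "averted" treatment costs — more people treated, more spending. This is
  deliberate, matches the printed formula, and explains why broader design
  options can have lower monetary benefits despite more launches. The
  blanket non-negativity that holds for the five health-outcome series
  does not extend to this one, and the tests pin both facts.

Benefits are computed per Monte Carlo run from that run's launches and then
averaged across runs, rather than pushing mean launch counts through the
nonlinear attribution rule; same estimand, cleaner statistics.

## Costs and economics

Mechanism operating costs are US$25/40/60 million per year for options
1/2/3 with a one-time start-up of 45% of annual operations in the first
year; options 2 and 3 invest US$100/250 million per year in health-system
strengthening for the first five years. Vaccine procurement follows the
dose equation literally: doses = cases averted / efficacy (E = 0.75),
priced at US$10 each. No population-coverage dosing model is substituted,
despite the equation's unusual epidemiology — the point of this layer is
fidelity, and both the efficacy and price are exposed in
`vaccine_params()`. The *societal* perspective includes procurement; the
*altruistic investor* perspective excludes it (countries are assumed to
pay for vaccines).

All streams — costs, monetary benefits and health outcomes — are
discounted at 3% per year. The discount base year is 2019 (the simulation
start; no base year is stated in the source material), and an
`discount_outcomes = FALSE` toggle reports undiscounted DALYs/deaths, since
published ratio tables are only approximately reproducible under either
convention. Headline quantities: BCR = discounted treatment costs averted /
discounted net costs; cost per DALY and per death averted; and the ICER
between design options, Δcost/ΔDALYs.

# The synthetic-data generator

The portfolio and disease-burden inputs of the original analysis live in a
supplementary appendix that is not machine-readable. The generator emulates
their *structure*:

* **Portfolios** honour every published marginal exactly: option 1 has 116
  vaccine candidates split 23/63/30 across preclinical/phase I/phase II;
  option 2 has 327 candidates with the printed per-disease counts
  (272/16/14/9/9/5/2); option 3 has 506 candidates with the printed
  disease shares (malaria 19%, TB 17%, HIV 17%, Ebola 14%, the non-Chagas
  NTDs jointly 11.5%, remainder uniform). Cells the source leaves
  unconstrained — archetype within a class, phase within options 2–3 — are
  filled multinomially under a configurable split (default: uniform within
  class; option 1's phase proportions 20/54/26 reused for options 2–3).
  Option 2 covers vaccine and therapeutic archetypes (the design-option
  table prints "diagnostics" for option 2, but the abstract and methods
  text both restrict it to vaccines and therapeutics; the text is
  followed).
* **Disease parameters** are drawn uniformly from plausible global ranges
  (incidence 0.2–5 million cases per age group-year, untreated case
  fatality 2–30%, disability weights 0.1–0.6, treatment cost US$20–200 per
  case, five age groups 0–4/5–14/15–49/50–69/70+ with age-appropriate
  residual life expectancy). Ordering constraints are enforced *by
  construction* — treated case fatality, disability weight and duration
  are drawn as fractions of their untreated counterparts — so every draw
  satisfies the model's invariants, which a property test verifies over
  many seeds.

What a green test does **not** establish: the synthetic world reproduces
the published marginal *structure*, not the appendix's actual burden
tables, so absolute DALYs/deaths from `run_scenario()` are not comparable
to the published absolutes. The reproducible published quantities — the
ratio arithmetic connecting net costs, benefits and outcomes — are checked
directly in the acceptance suite from the published values themselves.

# Parameters at a glance

| Parameter | Default | Units | Why |
|---|---|---|---|
| horizon | 2019–2030 | calendar years | simulation window of the analysis |
| benefits end | 2035 | calendar year | stated benefit accrual window |
| `n_runs` | 100 | runs | published Monte Carlo count |
| replenishment | 10/archetype/yr, 2019–2023 | candidates | stated assumption |
| ramp step | 0.10 | fraction of base per year | stated vaccine/coverage increment |
| ramp cap | 0.90 | fraction | stated maxima |
| discount rate | 0.03 | per year | stated rate |
| vaccine efficacy | 0.75 | — | stated procurement assumption |
| dose price | 10 | 2020 USD | stated procurement assumption |
| ops cost | 25/40/60 | USD m/yr by option | stated |
| start-up | 45% of ops | one-time | stated |
| HSS | 0/100/250, first 5 yrs | USD m/yr | stated |
| adaptive share | 0.5 or 1.0 | fraction of trials | −3/−6 months per phase, −7.5/−15% phase III cost |

Mechanism operating years default to the full simulation window 2019–2030;
the source never states when operations end, so this is exposed via
`mechanism_cost_params(ops_years = ...)` as a sensitivity knob.

# Known limitations

* No queueing or funding-capacity constraints (stages have infinite
  capacity by assumption), no competition between similar products, no
  herd-immunity or transmission dynamics, no age-targeted vaccination, and
  no productivity gains from reduced illness — all deliberately out of
  scope.
* Replenished candidates are assigned diseases uniformly over the option's
  disease list; the true entry mix is unknowable.
* Efficiency shares other than 50%/100% interpolate linearly between the
  two stated scenarios and are flagged with a message when used.
* The altruistic-perspective denominator includes operating, start-up and
  HSS costs alongside phase III spend; published per-DALY figures under
  that perspective are consistent with a phase III-only denominator for
  option 1 but not reconstructible for options 2–3, so the full-cost
  definition is used uniformly.
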