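---
title: "A Markov cohort cost-utility model of CBT for generalized anxiety disorder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort cost-utility model of CBT for generalized anxiety disorder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gadcea)
library(dplyr)
```

## The model

`gadcea` implements a deterministic Markov cohort model of generalized
anxiety disorder (GAD) progression combined with a cost-utility layer. A
cohort of 100,000 U.S. adults with GAD, starting at age 38, moves between
seven health states in 3-month cycles:

* four severity states defined by GAD-7 cut-off scores — no anxiety (0–4),
  mild (5–9), moderate (10–14), severe (15–21);
* moderate and severe anxiety *with comorbidities* (major depressive
  disorder and/or substance abuse), reachable only after the first cycle;
* dead, which is absorbing.

Each cycle a person can move to an adjacent severity state, enter or leave a
comorbidity state, stay put, or die. Behavioural transitions and mortality
are composed sequentially within a cycle: the behavioural row is applied
first, then every living state's row is scaled by `1 - q` and the remainder
sent to death, where `q` is the age-specific 3-month background death
probability. In the two comorbidity states `q` is multiplied by a
suicide-hazard multiplier (default 2.0), reflecting the elevated suicide
risk of comorbid GAD.

Three intervention strategies are compared:

* **mobile CBT** — an app-delivered guided self-help program ($150,
  3 months). Its state-specific efficacy is estimated from paired GAD-7
  screens of a pilot program: 70% of participants *clinically respond*,
  meaning they move to a strictly lower severity state by month 3.
* **traditional CBT** — face-to-face therapy ($1,200 for a 10-session
  course). Trial evidence provides only an overall 42% response rate; it is
  distributed over the severity states by scaling the mobile program's
  state-specific response structure with a common factor so the
  start-distribution-weighted mean equals 42%.
* **status quo** — no CBT; background pharmacotherapy (58.6% of the cohort,
  $105 per 3 months) and state-specific healthcare utilization continue.

An intervention is encoded as *replacement transition rows*: while the
effect lasts, the mild/moderate/severe rows of the status-quo matrix are
replaced by rows that place the response probability on the next-lower
state and spread the remaining mass over the status-quo row's non-improving
destinations in proportion to their status-quo probabilities. The effect is
fully sustained for the first year (4 cycles) and then *wanes*: the cycle
matrix is the convex combination `w·P_int + (1-w)·P_sq` with `w` declining
linearly from 1 to 0 between cycle 4 and the waning end (the model horizon
by default, cycle 8 in the 2-year sensitivity variant).

Costs are accumulated by component — age-banded baseline (non-GAD) care,
physician visits, ER visits, hospitalizations, pharmacotherapy,
disability-day productivity losses, and program cost — and discounted at 3%
per year along with QALYs (state utility × 0.25 per cycle). The societal
perspective includes disability days at the average daily wage ($206); the
payer perspective excludes them, and the two obey the exact identity
`payer total + disability component = societal total`. All dollar values
are 2016 USD; `adjust_to_currency_year()` rescales inputs quoted in other
years with the packaged CPI-U series.

## Scenarios

Three targeting scenarios differ only in the starting distribution:
*base* (mild 32.3%, moderate 44.6%, severe 23.1% — prevention and
treatment), *prevention only* (100% mild), and *treatment only* (moderate
65.9%, severe 34.1%).

## Synthetic inputs and what they can support

Two of the model's input tables come from primary sources that are not
publicly available: the transition/efficacy table and the per-state
3-month utilization counts. The packaged files
(`inst/extdata/*_synthetic.csv`) are therefore **synthetic stand-ins**, not
transcriptions, and the package's headline numbers should be read as
*model-structure* results, not as a reproduction of the original study's
numbers:

* The 12 status-quo behavioural probabilities and a single mortality-scale
  factor were calibrated once (see `tools/calibrate_transitions.R` in the
  source repository) so that the *no-intervention* cohort reproduces the
  published status-quo per-person life-year profile (19.57 / 11.42 / 2.51 /
  4.46 / 0.66 / 2.12 years from no-anxiety to severe-comorbid, ~40.7 years
  total). The fit achieves those values within ~0.5%.
* Utilization counts and disability days were anchored so the
  no-intervention cohort's discounted lifetime totals match the published
  status-quo cost levels (≈$25.5B payer, ≈$41B societal for the cohort).
* The mobile CBT rows are rebuilt from the pilot's 70% response applied
  uniformly to the three treated states; only the overall response rate is
  published, so uniformity is a modelling choice.

Everything *comparative* — QALY gains, cost reductions, thresholds — is
out-of-sample with respect to this calibration. Under the replacement-row
semantics a 70% per-cycle response sustained (with linear waning) over the
cohort lifetime is a very strong intervention: the mobile cohort
accumulates ~36 no-anxiety years per person against the published ~27.9,
and consequently the model's intervention-vs-status-quo deltas are several
times larger than the published ones, while the mobile-vs-traditional
comparisons (which difference away most of this) land close to the
published values. The original state-specific efficacy table would be
needed to close that gap; the package deliberately keeps the stand-ins
fixed rather than tuning them against comparative results.

The synthetic pilot generator (`simulate_pilot()`) emulates the pilot
study's design — n = 89, paired GAD-7 screens, the base-case severity mix
at intake, 70% response per state, non-responders remaining in their band —
and is the package's source of efficacy estimates. It draws scores
uniformly within severity bands (band membership, not the score itself,
drives the model) and does not model enrollment, attrition, or per-item
GAD-7 responses. Tests that pass against it demonstrate estimator
correctness and model behaviour, not clinical effectiveness of any real
program.

## Numerical and design choices

* **Horizon**: 288 cycles (age 38 to 110). Mass still alive at the cap
  contributes a terminal half-cycle of rewards; with default mortality this
  residual is negligible.
* **No half-cycle correction** on state membership: costs and QALYs use
  cycle-start occupancy and cycle-start age. This keeps rewards and
  transitions exactly aligned and is documented so it can be revisited.
* **Cycle-0 gating**: transitions into the comorbidity states are zeroed
  (with row renormalisation) in the first cycle's matrix, so comorbidity
  occupancy is exactly zero at cycles 0 and 1.
* **Stochasticity guard**: every constructed cycle matrix is renormalised
  and checked to row sums of 1 within 1e-12; cohort mass is conserved to
  well below 1e-6 persons over the full horizon.
* **Mortality table**: linear interpolation between tabulated ages, clamped
  to the stated 3-month bounds [0.0003, 0.0711], constant beyond the table.
* **Baseline non-GAD cost**: a step function over decennial age bands from
  $946/yr (under 45) to $5,154/yr (75+); only the endpoints are published,
  the band structure is a design choice.
* **Program cost accrual**: once, at cycle 0, for every participant (the
  published design enrolls the whole strategy arm immediately); under
  cycle-0 accrual discounting granularity is irrelevant to the comparison.
* **Preference rule for the threshold search**: "cost-effective" is
  operationalised as net monetary benefit at a configurable
  willingness-to-pay (default $100,000/QALY, the conventional U.S. value);
  a strict-dominance rule is also provided. The bisection resolves the
  traditional-CBT response threshold to 0.001.
* **Sweep ranges**: parameters with published ranges use them verbatim;
  utilization counts and the suicide multiplier default to ±20%, matching
  the pattern of the published ranges. Parameters without a range are not
  sweepable and `one_way_sweep()` refuses them by name.

## A worked run

```{r run, eval = FALSE}
params <- load_default_parameters()
grid <- run_all(params)
compare_grid(grid) |> filter(scenario == "base")
report_tables(grid)$totals

# deterministic sensitivity analysis
scenario_variant(params, "waning_2yr")
threshold_search(params)$threshold
one_way_sweep(params, "costs.disability_day") |> ggplot2::autoplot()
```

The same computations back the `cmd_run()` / `cmd_sweep()` / `cmd_pilot()`
entry points and the repository's `scripts/acceptance.R`, which re-runs the
full grid, the sensitivity variants and the pilot estimator and writes every
headline quantity as JSON.

## Known limitations

* The transition and utilization inputs are synthetic; absolute cost and
  QALY levels inherit their calibration assumptions (see above).
* Pharmacotherapy affects costs only, never transitions, and persists for
  life; combination effects of CBT and medication are not modelled.
* Program uptake is universal within a strategy arm; access effects are
  represented only through the status-quo comparison.
* The model is a cohort (expected-value) simulation: no individual-level
  heterogeneity, no probabilistic sensitivity analysis — the published
  analysis it follows is likewise deterministic.
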