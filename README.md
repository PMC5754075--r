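# gadcea

Cost-effectiveness modelling of cognitive behavioral therapy (CBT) for
generalized anxiety disorder (GAD).

GAD is a chronic anxiety condition affecting ~3% of U.S. adults; it is
treatable with CBT, but face-to-face therapy is expensive and hard to
access. App-delivered ("mobile") CBT programs promise similar clinical
response at a fraction of the cost. `gadcea` is for health-economics and
mental-health-services researchers who want to quantify that trade-off: it
implements a deterministic Markov cohort model that propagates 100,000
adults with GAD through seven GAD-7-derived health states in 3-month cycles
over the cohort lifetime, and attaches a full cost-utility layer (societal
and payer perspectives, 3% annual discounting).

**The core model.** Living states are the GAD-7 severity bands — no anxiety
(0–4), mild (5–9), moderate (10–14), severe (15–21) — plus moderate/severe
anxiety with psychiatric comorbidities and death. Each cycle the occupancy
row vector is multiplied by a cycle-specific transition matrix

> P(t) = mortality ∘ [ w(t)·P_int + (1 − w(t))·P_sq ]

where `P_sq` is the status-quo behavioural matrix, `P_int` replaces the
mild/moderate/severe rows with intervention rows that place the state's
clinical response probability on the next-lower severity state, and the
waning weight `w(t)` is 1 for the first year (4 cycles) then declines
linearly to 0 at the waning end. Mortality scales each living row by
`1 − q(age)` (with a suicide-hazard multiplier in the comorbidity states)
and sends the remainder to death. Discounted costs (baseline care,
physician/ER/hospital utilization, pharmacotherapy, disability days,
program cost) and QALYs are accumulated per cycle; strategies are compared
by cost reduction, QALY gain, dominance and ICER, with one-way sweeps,
scenario variants and a response-rate threshold search for deterministic
sensitivity analysis. A synthetic pilot generator produces paired GAD-7
screens (n = 89 by default, 70% clinical response) from which the mobile
program's state-specific efficacy is estimated.

Two input tables (severity transitions and per-state utilization counts)
derive from sources that are not publicly available; the packaged versions
are calibrated **synthetic stand-ins** (`inst/extdata/*_synthetic.csv`),
documented in the vignette (`vignettes/gad-cbt-model.Rmd`). Comparative
results are therefore model-structure results, not a reproduction of any
specific study's numbers.

## A worked example

```r
library(gadcea)
library(dplyr)

params <- load_default_parameters()
grid <- run_all(params) # 3 strategies x 3 scenarios x 2 perspectives

compare_grid(grid) |>
  filter(scenario == "base", perspective == "societal") |>
  select(comparator, delta_cost, delta_qalys, verdict)
#> # A tibble: 2 × 4
#>   comparator        delta_cost delta_qalys verdict
#>   <chr>                  <dbl>       <dbl> <chr>
#> 1 traditional_cbt  2462536269.      20363. cost_saving
#> 2 status_quo      24338102323.     157324. cost_saving

report_tables(grid)$totals
#> # A tibble: 6 × 5
#>   perspective scenario        mobile_cbt traditional_cbt status_quo
#>   <chr>       <chr>                <dbl>           <dbl>      <dbl>
#> 1 societal    base                  16.6            19.1       41
#> 2 societal    prevention_only       15.9            17.3       29.9
#> 3 societal    treatment_only        17              20         46.2
#> 4 payer       base                  13.6            14.8       25.5
#> 5 payer       prevention_only      13.2             13.9       20
#> 6 payer       treatment_only       13.8             15.2       28.1
```

Read: in the base case the mobile program is *cost-saving* (dominant)
against both comparators — it reduces discounted lifetime societal costs by
$2.46B versus traditional CBT while adding ~20,400 QALYs across the cohort,
and the cohort's total discounted societal cost falls from $41.0B (no CBT)
to $16.6B. Totals are in billions of dollars.

Estimating efficacy from (synthetic) pilot data:

```r
eff <- estimate_efficacy(simulate_pilot(n = 89, seed = 20180104))
glance(eff)
#> # A tibble: 1 × 3
#>   overall_response n_used n_excluded
#>              <dbl>  <int>      <int>
#> 1            0.663     89          0
```

At n = 89 the estimate is noisy around the generating 70% — exactly the
uncertainty a pilot of that size carries. `mobile_cbt_strategy(params,
efficacy = eff)` plugs the estimate into the model.

Sensitivity analysis and plotting:

```r
scenario_variant(params, "waning_2yr")   # effects decay over 2 years
threshold_search(params)$threshold       # traditional-CBT response rate
                                         # at which it becomes preferred
ggplot2::autoplot(one_way_sweep(params, "costs.disability_day"))
ggplot2::autoplot(tornado_summary(params))
```

Shell entry points (`run`, `sweep`, `pilot` subcommands) wrap the same
functions:

```sh
Rscript inst/cli/gadcea.R run --out report/
Rscript inst/cli/gadcea.R sweep --parameter costs.er_visit
Rscript inst/cli/gadcea.R pilot --n 89 --seed 7
```

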