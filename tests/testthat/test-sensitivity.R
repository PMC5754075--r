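test_that("sweeps are pure and a default-valued sweep equals the base run", {
  p <- default_params()
  p$horizon_cycles <- 80L
  snapshot <- p
  base_grid <- run_all(p, scenarios = "base", perspectives = "societal")
  base_cmp <- compare_grid(base_grid)

  sw <- one_way_sweep(p, "costs.er_visit", values = c(625, 782, 938))
  expect_identical(p, snapshot) # input untouched
  after <- run_all(p, scenarios = "base", perspectives = "societal")
  expect_identical(base_grid$cost_total, after$cost_total)

  # the default-valued point of the sweep reproduces the base comparisons
  at_default <- sw[sw$value == 782, ]
  expect_equal(
    at_default$delta_cost[at_default$comparator == "status_quo"],
    base_cmp$delta_cost[base_cmp$comparator == "status_quo"]
  )
  expect_error(one_way_sweep(p, "not.a.parameter"), "not sweepable")
  expect_error(one_way_sweep(p, "costs.er_visit", values = numeric(0)), "non-empty")
})

test_that("a monotone cost parameter produces monotone cost deltas", {
  p <- default_params()
  p$horizon_cycles <- 80L
  # traditional CBT course cost only raises traditional's total: the mobile
  # vs traditional saving must increase monotonically
  sw <- one_way_sweep(p, "costs.cbt_course", values = c(960, 1200, 1440))
  d <- sw[sw$comparator == "traditional_cbt", ]
  expect_true(all(diff(d$delta_cost[order(d$value)]) > 0))
  # while the mobile vs status-quo saving is untouched
  d2 <- sw[sw$comparator == "status_quo", ]
  expect_equal(diff(range(d2$delta_cost)), 0)
})

test_that("raising the mobile program cost far enough flips the status-quo verdict", {
  p <- default_params()
  p$horizon_cycles <- 60L
  base_cmp <- compare_grid(run_all(p, scenarios = "base", perspectives = "societal"))
  saving <- base_cmp$delta_cost[base_cmp$comparator == "status_quo"]
  per_person <- saving / p$cohort_size

  # bisect the program cost to the break-even point on the monotone cost
  # difference, then verify the sign change around it
  delta_at <- function(cost) {
    p2 <- param_set(p, "costs.mobile_program", cost)
    cmp <- compare_grid(run_all(p2, scenarios = "base", perspectives = "societal"))
    cmp$delta_cost[cmp$comparator == "status_quo"]
  }
  lo <- 150
  hi <- 150 + 2 * per_person
  expect_gt(delta_at(lo), 0)
  expect_lt(delta_at(hi), 0)
  for (i in 1:25) {
    mid <- (lo + hi) / 2
    if (delta_at(mid) > 0) lo <- mid else hi <- mid
  }
  crossing <- (lo + hi) / 2
  # the program cost is a cycle-0 per-person cost, so break-even sits at the
  # original cost plus the per-person saving (undiscounted at cycle 0)
  expect_equal(crossing, 150 + per_person, tolerance = 1e-4)
})

test_that("scenario variants apply their documented modification", {
  p <- default_params()
  p$horizon_cycles <- 80L
  base <- scenario_variant(p, "none")
  soc <- function(cmp, comparator = "traditional_cbt") {
    cmp[cmp$perspective == "societal" & cmp$comparator == comparator, ]
  }

  # a variant that changes nothing reproduces the base comparisons
  again <- scenario_variant(p, "none")
  expect_equal(base$delta_cost, again$delta_cost)

  # 2-year waning: the program's effect dies out quickly, so the QALY gain
  # over no intervention shrinks
  w2 <- scenario_variant(p, "waning_2yr")
  expect_lt(
    soc(w2, "status_quo")$delta_qalys,
    soc(base, "status_quo")$delta_qalys
  )

  # degraded mobile efficacy: smaller QALY gain over no intervention
  deg <- scenario_variant(p, "mobile_eff_minus20")
  expect_lt(
    soc(deg, "status_quo")$delta_qalys,
    soc(base, "status_quo")$delta_qalys
  )

  # 80%-productive disability days: societal savings shrink toward payer's
  disab <- scenario_variant(p, "disability_80pct_productive")
  expect_lt(soc(disab)$delta_cost, soc(base)$delta_cost)
  pay <- function(cmp) cmp[cmp$perspective == "payer" & cmp$comparator == "traditional_cbt", ]
  expect_equal(pay(disab)$delta_cost, pay(base)$delta_cost) # payer unaffected
  expect_gt(soc(disab)$delta_cost, pay(disab)$delta_cost)

  # suicide risk in all anxiety states: mobile CBT stays dominant
  suic <- scenario_variant(p, "suicide_risk_all_states")
  expect_true(all(suic$verdict == "cost_saving"))

  expect_error(scenario_variant(p, "not_a_variant"))
})

test_that("threshold search obeys its preference rules", {
  p <- default_params()
  p$horizon_cycles <- 60L

  # strict dominance when traditional matches mobile's response rate but
  # costs more: never preferred
  dom <- threshold_search(p, rule = "dominance", lower = 0.70, upper = 0.70)
  expect_true(is.na(dom$threshold))

  # a cheaper, equally effective traditional program is preferred
  # immediately at the lower end of the search interval
  p_cheap <- p
  p_cheap$costs$cbt_course <- 0
  cheap <- threshold_search(p_cheap, rule = "nmb", lower = 0.70, upper = 1)
  expect_equal(cheap$threshold, 0.70)

  # default rule: a threshold exists, is above the traditional default and
  # the comparison flips across it
  th <- threshold_search(p, rule = "nmb", wtp = 1e5)
  expect_gt(th$threshold, 0.42)
  expect_lte(th$threshold, 1)
  nmb_gap <- function(rate) {
    trad <- traditional_cbt_strategy(p, overall_response = rate)
    mob <- mobile_cbt_strategy(p)
    o <- function(s) {
      accumulate(run_cohort(p, s, "base"), p, s, "societal")
    }
    ot <- o(trad)
    om <- o(mob)
    (1e5 * ot$qalys - ot$cost_total) - (1e5 * om$qalys - om$cost_total)
  }
  expect_lt(nmb_gap(th$threshold - 0.01), 0)
  expect_gte(nmb_gap(th$threshold), 0)
})

test_that("tornado summary spans each parameter's range", {
  p <- default_params()
  p$horizon_cycles <- 60L
  tor <- tornado_summary(p,
    parameters = c("costs.disability_day", "costs.mobile_program"),
    comparator = "status_quo"
  )
  expect_equal(nrow(tor), 2)
  # disability-day cost moves societal savings far more than the mobile
  # program's own cost
  span <- abs(tor$delta_cost_high - tor$delta_cost_low)
  expect_gt(
    span[tor$parameter == "costs.disability_day"],
    span[tor$parameter == "costs.mobile_program"]
  )
})
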