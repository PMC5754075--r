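grid_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_all(default_params())
    cache
  }
})

test_that("run_all produces the complete deterministic grid", {
  grid <- grid_cache()
  expect_equal(nrow(grid), 3 * 3 * 2)
  expect_setequal(unique(grid$strategy), c("mobile_cbt", "traditional_cbt", "status_quo"))
  # deterministic: a second run reproduces the numbers exactly
  grid2 <- run_all(default_params())
  expect_equal(grid$cost_total, grid2$cost_total)
  expect_equal(grid$qalys, grid2$qalys)
  expect_error(run_all(default_params(), strategies = list()), "non-empty")
})

test_that("an identical strategy listed twice yields identical outcomes", {
  p <- default_params()
  p$horizon_cycles <- 60L
  twice <- list(a = mobile_cbt_strategy(p), b = mobile_cbt_strategy(p))
  g <- run_all(p, strategies = twice, scenarios = "base", perspectives = "societal")
  expect_equal(g$cost_total[1], g$cost_total[2])
  expect_equal(g$qalys[1], g$qalys[2])
})

test_that("zero costs everywhere give zero totals", {
  p <- zero_cost_params(default_params())
  p$horizon_cycles <- 40L
  g <- run_all(p, scenarios = "base")
  expect_true(all(g$cost_total == 0))
  expect_true(all(g$qalys > 0))
})

test_that("comparisons follow the savings convention and dominance logic", {
  p <- default_params()
  grid <- grid_cache()
  a <- grid_outcome(grid, "mobile_cbt", "base", "societal")
  b <- grid_outcome(grid, "status_quo", "base", "societal")
  cmp <- compare(a, b)
  expect_equal(cmp$delta_cost, b$cost_total - a$cost_total)
  expect_equal(cmp$delta_qalys, a$qalys - b$qalys)

  # self-comparison: zero deltas
  self <- compare(a, a)
  expect_equal(self$delta_cost, 0)
  expect_equal(self$delta_qalys, 0)
  expect_equal(self$verdict, "equivalent")

  # mismatched context refuses to compare
  c_payer <- grid_outcome(grid, "status_quo", "base", "payer")
  expect_error(compare(a, c_payer), "share scenario and perspective")

  # hand-built outcomes: dominance and ICER logic
  mk <- function(cost, qalys) {
    structure(list(
      strategy = "x", scenario = "base", perspective = "societal",
      cost_total = cost, qalys = qalys
    ), class = "gad_outcome")
  }
  expect_equal(compare(mk(100, 10), mk(200, 5))$verdict, "cost_saving")
  expect_equal(compare(mk(200, 5), mk(100, 10))$verdict, "dominated")
  icer_row <- compare(mk(200, 10), mk(100, 5)) # costs 100 more, gains 5
  expect_equal(icer_row$verdict, "icer")
  expect_equal(icer_row$icer, 20)
})

test_that("two-cycle toy deltas match hand arithmetic", {
  # frozen cohort, 2 cycles, no discounting, no mortality beyond q
  q <- 0
  p <- flat_params(q = 0.0003, horizon = 2L) # minimum allowed mortality
  p$discount_rate <- 0
  p <- zero_cost_params(p)
  p$costs$mobile_program <- 100
  p$costs$cbt_course <- 400
  rows <- p$transitions$mobile_cbt # identity rows in the frozen toy
  strategies <- list(
    mobile_cbt = new_strategy("mobile_cbt", rows, program_cost = 100),
    traditional_cbt = new_strategy("traditional_cbt", rows, program_cost = 400),
    status_quo = status_quo_strategy()
  )
  g <- run_all(p, strategies = strategies, scenarios = "base", perspectives = "payer")
  a <- grid_outcome(g, "mobile_cbt", "base", "payer")
  b <- grid_outcome(g, "traditional_cbt", "base", "payer")
  s <- grid_outcome(g, "status_quo", "base", "payer")
  # identity transitions: the only cost is the cycle-0 program cost
  expect_equal(compare(a, b)$delta_cost, (400 - 100) * 1e5)
  expect_equal(compare(a, s)$delta_cost, -100 * 1e5)
  # identical health trajectories => zero QALY deltas
  expect_equal(compare(a, b)$delta_qalys, 0)
})

test_that("report tables mirror the published layout and the grid's numbers", {
  grid <- grid_cache()
  rep <- report_tables(grid)
  expect_named(rep, c("reductions", "life_years", "totals"))
  expect_equal(nrow(rep$reductions), 12) # 2 comparators x 3 scenarios x 2 perspectives
  expect_equal(nrow(rep$life_years), 18) # 6 states x 3 scenarios
  expect_equal(nrow(rep$totals), 6) # 3 scenarios x 2 perspectives

  # internal arithmetic consistency: a reductions cell equals the difference
  # of the corresponding totals, at reporting precision
  cmp <- compare_grid(grid)
  for (i in seq_len(nrow(rep$reductions))) {
    row <- rep$reductions[i, ]
    j <- which(cmp$comparator == row$comparator & cmp$scenario == row$scenario &
      cmp$perspective == row$perspective)
    expect_equal(row$cost_reduction_million, round(cmp$delta_cost[j] / 1e6))
    expect_equal(row$qaly_improvement, round(cmp$delta_qalys[j]))
  }

  # life-years table agrees with the outcomes, rounded to 2 dp
  sq_no_anx <- grid_outcome(grid, "status_quo", "base", "societal")$life_years[["NO_ANX"]]
  cell <- rep$life_years[rep$life_years$scenario == "base" &
    rep$life_years$state == "NO_ANX", ]
  expect_equal(cell$status_quo, round(sq_no_anx, 2))

  # incomplete grid is refused with the missing cell named
  part <- run_all(default_params(), scenarios = "base")
  expect_error(report_tables(part), "missing cell")
})

test_that("QALY gains order as treatment-only > base > prevention-only", {
  cmp <- compare_grid(grid_cache()) |>
    dplyr::filter(.data$perspective == "societal")
  for (comparator in c("traditional_cbt", "status_quo")) {
    d <- cmp[cmp$comparator == comparator, ]
    dq <- setNames(d$delta_qalys, d$scenario)
    expect_gte(dq[["treatment_only"]], dq[["base"]])
    expect_gte(dq[["base"]], dq[["prevention_only"]])
  }
})

test_that("report tables write one CSV per table", {
  dir <- withr::local_tempdir()
  paths <- write_report_tables(report_tables(grid_cache()), dir)
  expect_true(all(file.exists(paths)))
  back <- readr::read_csv(paths[["totals"]], show_col_types = FALSE)
  expect_equal(nrow(back), 6)
})
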