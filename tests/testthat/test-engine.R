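test_that("waning weight is 1 through the full-effect window, linear after, 0 at the end", {
  s <- new_strategy("x",
    intervention_matrix = NULL, waning_full_effect_cycles = 4,
    waning_end_cycle = 100
  )
  expect_equal(waning_weight(2, s, 288), 1)
  expect_equal(waning_weight(4, s, 288), 1)
  expect_equal(waning_weight(100, s, 288), 0)
  expect_equal(waning_weight(150, s, 288), 0)
  expect_equal(waning_weight(52, s, 288), 0.5) # midpoint of (4, 100)
  # quarter points of the decline
  expect_equal(waning_weight(28, s, 288), 0.75)
  expect_equal(waning_weight(76, s, 288), 0.25)
  # NULL waning_end_cycle falls back to the horizon
  s2 <- new_strategy("y", waning_full_effect_cycles = 4)
  expect_equal(waning_weight(146, s2, 288), 0.5)
  expect_error(
    new_strategy("z", waning_full_effect_cycles = 10, waning_end_cycle = 8),
    "must not exceed"
  )
})

test_that("cycle matrices blend intervention and status-quo rows by the waning weight", {
  p <- default_params()
  sq <- p$transitions$status_quo
  mob <- mobile_cbt_strategy(p, waning_end_cycle = 8)

  # full effect: treated rows equal the intervention rows exactly
  m_full <- build_cycle_matrix(p, mob, cycle = 2, age = 38.5)
  q <- mortality_q(p, 38.5)
  for (s in c("MILD", "MOD", "SEV")) {
    expect_equal(
      m_full[s, gad_living_states()],
      p$transitions$mobile_cbt[s, gad_living_states()] * (1 - q)
    )
  }
  # untreated rows always follow status quo
  expect_equal(m_full["NO_ANX", gad_living_states()], sq["NO_ANX", gad_living_states()] * (1 - q))

  # half-waned: entrywise mean of the two behavioural matrices
  m_half <- build_cycle_matrix(p, mob, cycle = 6, age = 39.5)
  q6 <- mortality_q(p, 39.5)
  for (s in c("MILD", "MOD", "SEV")) {
    blended <- 0.5 * p$transitions$mobile_cbt[s, gad_living_states()] +
      0.5 * sq[s, gad_living_states()]
    expect_equal(m_half[s, gad_living_states()], blended * (1 - q6))
  }

  # fully waned: identical to the status-quo matrix
  m_done <- build_cycle_matrix(p, mob, cycle = 8, age = 40)
  m_sq <- build_cycle_matrix(p, status_quo_strategy(), cycle = 8, age = 40)
  expect_identical(m_done, m_sq)
})

test_that("a strategy whose rows equal status quo reproduces status quo exactly", {
  p <- default_params()
  sq_rows <- p$transitions$status_quo
  sq_rows[c("NO_ANX", "MOD_COMORB", "SEV_COMORB", "DEAD"), ] <- 0
  clone <- new_strategy("clone", intervention_matrix = sq_rows, program_cost = 0,
    program_cycles = 0L)
  for (cyc in c(0, 1, 5, 100)) {
    age <- 38 + 0.25 * cyc
    expect_identical(
      build_cycle_matrix(p, clone, cyc, age),
      build_cycle_matrix(p, status_quo_strategy(), cyc, age)
    )
  }
  tr_clone <- run_cohort(p, clone, "base")
  tr_sq <- run_cohort(p, status_quo_strategy(), "base")
  expect_identical(tr_clone$persons, tr_sq$persons)
})

test_that("cycle-0 matrix admits no comorbidity entry and rows stay stochastic", {
  p <- default_params()
  entry_rows <- c("NO_ANX", "MILD", "MOD", "SEV")
  for (strat in default_strategies(p)) {
    m0 <- build_cycle_matrix(p, strat, cycle = 0, age = 38)
    expect_true(all(m0[entry_rows, gad_comorbidity_states()] == 0))
    expect_stochastic(m0)
    m1 <- build_cycle_matrix(p, strat, cycle = 1, age = 38.25)
    expect_gt(sum(m1[, gad_comorbidity_states()]), 0)
    expect_stochastic(m1)
  }
})

test_that("mortality is applied per state with the suicide multiplier in comorbidity states", {
  p <- default_params()
  age <- 60
  q <- mortality_q(p, age)
  m <- build_cycle_matrix(p, status_quo_strategy(), cycle = 10, age = age)
  expect_equal(unname(m["MILD", "DEAD"]), q)
  expect_equal(unname(m["SEV", "DEAD"]), q)
  expect_equal(unname(m["MOD_COMORB", "DEAD"]), min(1, q * p$suicide_multiplier))
  expect_equal(unname(m["SEV_COMORB", "DEAD"]), min(1, q * p$suicide_multiplier))
  expect_equal(unname(m["DEAD", "DEAD"]), 1)

  # extending the suicide states moves the extra hazard to MOD/SEV too
  p2 <- p
  p2$suicide_states <- c("MOD", "SEV", gad_comorbidity_states())
  m2 <- build_cycle_matrix(p2, status_quo_strategy(), cycle = 10, age = age)
  expect_equal(unname(m2["MOD", "DEAD"]), min(1, q * p$suicide_multiplier))
  expect_equal(unname(m2["NO_ANX", "DEAD"]), q)
})

test_that("cohorts start in the scenario's distribution and conserve mass", {
  p <- default_params()
  mob <- mobile_cbt_strategy(p)
  start_of <- function(tr) {
    occ <- trace_occupancy(tr)
    occ[1, ]
  }
  tr_prev <- run_cohort(p, mob, "prevention_only")
  expect_equal(unname(start_of(tr_prev)[c("MILD", "MOD", "SEV")]), c(100000, 0, 0))
  tr_treat <- run_cohort(p, mob, "treatment_only")
  expect_equal(unname(start_of(tr_treat)[c("MILD", "MOD", "SEV")]), c(0, 65900, 34100))
  tr_base <- run_cohort(p, mob, "base")
  expect_equal(unname(start_of(tr_base)[c("MILD", "MOD", "SEV")]), c(32300, 44600, 23100))

  for (tr in list(tr_prev, tr_treat, tr_base)) {
    occ <- trace_occupancy(tr)
    expect_lt(max(abs(rowSums(occ) - 100000)), 1e-6)
    # DEAD is absorbing: monotone non-decreasing occupancy
    expect_true(all(diff(occ[, "DEAD"]) >= 0))
    # comorbidity states are empty at cycles 0 and 1
    expect_equal(unname(occ[1:2, gad_comorbidity_states()]), matrix(0, 2, 2))
    expect_gt(occ[3, "MOD_COMORB"], 0)
  }
})

test_that("life-years in a frozen-state cohort match the geometric closed form", {
  q <- 0.02
  H <- 60L
  p <- flat_params(q = q, horizon = H)
  tr <- run_cohort(p, status_quo_strategy(), "base")
  oc <- accumulate(tr, p, status_quo_strategy(), "societal")
  # survival is (1-q)^t; cycles 0..H-1 count 0.25 y, the horizon cap adds a
  # terminal half-cycle
  expected <- 0.25 * sum((1 - q)^(0:(H - 1))) + 0.125 * (1 - q)^H
  expect_equal(sum(oc$life_years), expected, tolerance = 1e-10)
  # states never mix, so life-years split in the starting proportions
  expect_equal(
    unname(oc$life_years[c("MILD", "MOD", "SEV")]) / expected,
    unname(p$start_distributions$base[c("MILD", "MOD", "SEV")]),
    tolerance = 1e-10
  )
})

test_that("the engine matches an independent matrix-power computation", {
  p <- default_params()
  p$horizon_cycles <- 40L
  # constant mortality and no comorbidity gating effect: time-homogeneous
  p$mortality_table <- data.frame(age = c(38, 120), q_3month = c(0.01, 0.01))
  p$suicide_multiplier <- 1
  set.seed(42)
  for (rep in 1:5) {
    p$transitions$status_quo <- random_behavioural_matrix(allow_comorbidity = FALSE)
    p2 <- validate_parameters(p)
    M <- build_cycle_matrix(p2, status_quo_strategy(), cycle = 1, age = 50)
    # cycle-0 matrix equals every later matrix here (no comorbidity columns)
    expect_equal(build_cycle_matrix(p2, status_quo_strategy(), 0, 38), M)
    tr <- run_cohort(p2, status_quo_strategy(), "base")
    occ <- trace_occupancy(tr)
    v <- occ[1, , drop = FALSE]
    powers <- diag(7)
    for (t in 1:40) powers <- powers %*% M
    expect_lt(max(abs(occ[41, ] - v %*% powers)), 1e-10 * p$cohort_size)
  }
})

test_that("raising a response rate never lowers no-anxiety life-years", {
  p <- default_params()
  p$horizon_cycles <- 120L
  base_rates <- c(MILD = 0.5, MOD = 0.5, SEV = 0.5)
  ly_no_anx <- function(rates) {
    s <- mobile_cbt_strategy(p, rates = rates)
    tr <- run_cohort(p, s, "base")
    accumulate(tr, p, s, "societal")$life_years[["NO_ANX"]]
  }
  ref <- ly_no_anx(base_rates)
  for (s in names(base_rates)) {
    for (bump in c(0.1, 0.3)) {
      up <- base_rates
      up[s] <- up[s] + bump
      expect_gte(ly_no_anx(up), ref)
    }
  }
})
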