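#' Discount factor for a model cycle
#'
#' Costs and QALYs are discounted at an annual rate; a cycle is a quarter
#' year, so cycle `t` is discounted by `(1 + rate)^(-0.25 t)`.
#'
#' @param cycle Cycle index (0-based); vectorised.
#' @param annual_rate Annual discount rate (>= 0).
#' @param cycle_length Cycle length in years (default 0.25).
#' @return Discount factor(s) in `(0, 1]`.
#' @export
#' @examples
#' discount_factor(c(0, 4, 8), 0.03)
discount_factor <- function(cycle, annual_rate, cycle_length = 0.25) {
  stopifnot(annual_rate >= 0)
  (1 + annual_rate)^(-cycle * cycle_length)
}

cost_components <- function() {
  c(
    "baseline_care", "physician", "er", "hospitalization", "pharma",
    "disability", "program"
  )
}

# Per-person per-cycle cost by component for every state (7 x 7 matrix:
# state x component). DEAD costs nothing. The program component applies to
# every living state while the program runs.
cycle_cost_matrix <- function(params, strategy, cycle, age, perspective) {
  states <- gad_states()
  m <- matrix(0, 7, length(cost_components()),
    dimnames = list(states, cost_components())
  )
  living <- gad_living_states()
  util <- params$utilization
  idx <- match(living, util$state)
  m[living, "baseline_care"] <- baseline_annual_cost(params, age) * params$cycle_length
  m[living, "physician"] <- util$physician_visits[idx] * params$costs$physician_visit
  m[living, "er"] <- util$er_visits[idx] * params$costs$er_visit
  m[living, "hospitalization"] <- util$hospitalizations[idx] * params$costs$hospitalization
  m[living, "pharma"] <- params$med_fraction * params$costs$pharma_3mo
  if (perspective == "societal") {
    m[living, "disability"] <- util$disability_days[idx] * params$costs$disability_day *
      params$disability_productivity_factor
  }
  if (cycle < strategy$program_cycles) {
    m[living, "program"] <- strategy$program_cost
  }
  m
}

#' Per-person cost of one cycle in a state
#'
#' Baseline (non-GAD) care for the cohort's age, state-specific healthcare
#' utilization (physician visits, ER visits, hospitalizations), background
#' pharmacotherapy for the medicated fraction, disability-day productivity
#' losses (societal perspective only), and the program cost while the
#' program runs. `DEAD` costs 0.
#'
#' @param state A health-state label.
#' @param age Age in years at the start of the cycle.
#' @param params A `gad_parameters` object.
#' @param strategy A `gad_strategy`.
#' @param cycle Cycle index (0-based).
#' @param perspective `"societal"` or `"payer"`.
#' @return Cost in model dollars per person for the cycle.
#' @export
cycle_cost <- function(state, age, params, strategy, cycle,
                       perspective = c("societal", "payer")) {
  perspective <- match.arg(perspective)
  m <- cycle_cost_matrix(params, strategy, cycle, age, perspective)
  sum(m[state, ])
}

#' Per-person QALYs accrued in one cycle in a state
#'
#' The state utility times the cycle length; `DEAD` contributes 0.
#'
#' @param state A health-state label.
#' @param params A `gad_parameters` object.
#' @return QALYs per person per cycle.
#' @export
#' @examples
#' p <- load_default_parameters()
#' cycle_qaly("NO_ANX", p) # 0.80 * 0.25
cycle_qaly <- function(state, params) {
  unname(params$utilities[state] * params$cycle_length)
}

#' Accumulate a cohort trace into economic outcomes
#'
#' Sums discounted costs (by component) and discounted QALYs over cycles
#' using cycle-start occupancy and cycle-start age, plus a terminal
#' half-cycle for mass still alive at the horizon. Life-years by state are
#' accumulated undiscounted and divided by the cohort size, giving
#' per-person years in each state.
#'
#' @param trace A `gad_trace` from [run_cohort()].
#' @param params A `gad_parameters` object.
#' @param strategy The `gad_strategy` that produced the trace.
#' @param perspective `"societal"` (includes disability-day costs) or
#'   `"payer"` (excludes them).
#' @return An object of class `gad_outcome`: a list with `cost_total`,
#'   `cost_by_component` (named vector), `qalys`, `life_years` (named
#'   per-person years by living state), and the run labels.
#' @export
accumulate <- function(trace, params, strategy,
                       perspective = c("societal", "payer")) {
  perspective <- match.arg(perspective)
  occ <- trace_occupancy(trace)
  H <- attr(trace, "horizon_cycles")
  if (any(abs(rowSums(occ) - params$cohort_size) > 1e-6 * params$cohort_size)) {
    stop("trace does not conserve cohort mass", call. = FALSE)
  }
  u <- params$utilities[gad_states()]
  cost_by_comp <- setNames(numeric(length(cost_components())), cost_components())
  qalys <- 0
  life_years <- setNames(numeric(7), gad_states())
  for (t in 0:H) {
    wt <- if (t == H) 0.5 else 1 # terminal half-cycle at the horizon cap
    age <- params$start_age + params$cycle_length * t
    dfac <- discount_factor(t, params$discount_rate, params$cycle_length)
    cm <- cycle_cost_matrix(params, strategy, t, age, perspective)
    cost_by_comp <- cost_by_comp + wt * dfac * as.vector(occ[t + 1, ] %*% cm)
    qalys <- qalys + wt * dfac * params$cycle_length * sum(occ[t + 1, ] * u)
    life_years <- life_years + wt * params$cycle_length * occ[t + 1, ]
  }
  life_years <- life_years[gad_living_states()] / params$cohort_size
  structure(
    list(
      strategy = attr(trace, "strategy"),
      scenario = attr(trace, "scenario"),
      perspective = perspective,
      cost_total = sum(cost_by_comp),
      cost_by_component = cost_by_comp,
      qalys = qalys,
      life_years = life_years,
      discount_rate = params$discount_rate,
      cohort_size = params$cohort_size
    ),
    class = "gad_outcome"
  )
}

#' @export
print.gad_outcome <- function(x, ...) {
  cat(sprintf(
    "<gad_outcome> %s / %s / %s\n  discounted cost $%.1fM, discounted QALYs %s, life expectancy %.2f y\n",
    x$strategy, x$scenario, x$perspective, x$cost_total / 1e6,
    format(round(x$qalys), big.mark = ","), sum(x$life_years)
  ))
  invisible(x)
}
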