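#' One-way deterministic sensitivity sweep
#'
#' Re-runs the full strategy grid at each value of one parameter, holding
#' everything else at its default, and records the pairwise comparisons of
#' mobile CBT against traditional CBT and status quo. Strategies are rebuilt
#' from the perturbed parameter set at every value, so sweeping a program
#' cost or a transition-relevant input propagates correctly. The input
#' parameter set is never modified.
#'
#' @param params A `gad_parameters` object.
#' @param parameter Flat parameter key (see [param_get()]); must be
#'   sweepable, i.e. listed in [parameter_ranges()].
#' @param values Numeric values to evaluate (default: the parameter's low,
#'   default and high from its declared range).
#' @param scenario Scenario to evaluate (default `"base"`).
#' @param perspective Perspective to evaluate (default `"societal"`).
#' @return A tibble of class `gad_sweep`: one row per value x comparator
#'   with the comparison columns of [compare()]; the `"verdict_flips"`
#'   attribute lists values whose verdict differs from the default value's
#'   verdict.
#' @export
one_way_sweep <- function(params, parameter, values = NULL,
                          scenario = "base", perspective = "societal") {
  ranges <- parameter_ranges(params)
  i <- match(parameter, ranges$parameter)
  if (is.na(i)) {
    stop("parameter is not sweepable: ", parameter, call. = FALSE)
  }
  if (is.null(values)) {
    values <- unique(c(ranges$low[i], ranges$default[i], ranges$high[i]))
  }
  if (length(values) == 0) stop("`values` must be non-empty", call. = FALSE)

  rows <- lapply(values, function(v) {
    p2 <- param_set(params, parameter, v)
    grid <- run_all(p2,
      scenarios = scenario,
      perspectives = perspective
    )
    cmp <- compare_grid(grid,
      reference = "mobile_cbt",
      comparators = c("traditional_cbt", "status_quo")
    )
    cmp$parameter <- parameter
    cmp$value <- v
    cmp
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::select("parameter", "value", dplyr::everything())

  ref_value <- ranges$default[i]
  ref_rows <- out[abs(out$value - ref_value) == min(abs(out$value - ref_value)), ]
  flips <- unique(out$value[vapply(seq_len(nrow(out)), function(j) {
    ref <- ref_rows$verdict[ref_rows$comparator == out$comparator[j]][1]
    !identical(out$verdict[j], ref)
  }, logical(1))])
  attr(out, "verdict_flips") <- flips
  class(out) <- c("gad_sweep", class(out))
  out
}

#' Scenario variants of the published sensitivity analysis
#'
#' Applies one documented modification and returns the base-case pairwise
#' comparisons (mobile CBT vs traditional CBT and vs status quo) under both
#' perspectives:
#' * `waning_2yr` — both CBT programs' effects decay to status quo over 2
#'   years (waning ends at cycle 8) instead of over the cohort lifetime;
#' * `mobile_eff_minus20` — every mobile CBT state-specific response rate is
#'   multiplied by 0.8;
#' * `disability_80pct_productive` — individuals are assumed 80% productive
#'   on a disability day, so each day costs 20% of the full daily wage;
#' * `suicide_risk_all_states` — the suicide-hazard multiplier also applies
#'   to the non-comorbid moderate and severe anxiety states;
#' * `none` — no modification (returns the base comparisons unchanged).
#'
#' @param params A `gad_parameters` object.
#' @param variant One of the variant names above.
#' @param scenario Scenario to evaluate (default `"base"`).
#' @return Tibble of comparison rows (one per comparator x perspective).
#' @export
scenario_variant <- function(params,
                             variant = c(
                               "waning_2yr", "mobile_eff_minus20",
                               "disability_80pct_productive",
                               "suicide_risk_all_states", "none"
                             ),
                             scenario = "base") {
  variant <- match.arg(variant)
  strategies <- default_strategies(params)
  if (variant == "waning_2yr") {
    strategies <- default_strategies(params, waning_end_cycle = 8L)
  } else if (variant == "mobile_eff_minus20") {
    rates <- 0.8 * strategy_response_rates(params$transitions$mobile_cbt)
    strategies$mobile_cbt <- mobile_cbt_strategy(params, rates = rates)
  } else if (variant == "disability_80pct_productive") {
    params$disability_productivity_factor <- 0.2
  } else if (variant == "suicide_risk_all_states") {
    params$suicide_states <- c("MOD", "SEV", gad_comorbidity_states())
  }
  params <- validate_parameters(params)
  grid <- run_all(params, strategies, scenarios = scenario)
  cmp <- compare_grid(grid,
    reference = "mobile_cbt",
    comparators = c("traditional_cbt", "status_quo")
  )
  cmp$variant <- variant
  dplyr::select(cmp, "variant", dplyr::everything())
}

#' Threshold search on the traditional CBT response rate
#'
#' Finds the smallest overall clinical response rate in `(lower, upper]` at
#' which traditional CBT becomes preferred over mobile CBT, by bisection to
#' `tol`. The preference rule is configurable:
#' * `"nmb"` (default) — traditional CBT is preferred when its net monetary
#'   benefit (`wtp * QALYs - cost`) is at least mobile CBT's;
#' * `"dominance"` — traditional CBT is preferred only when it strictly
#'   dominates (lower cost and at least as many QALYs).
#'
#' @param params A `gad_parameters` object.
#' @param rule Preference rule.
#' @param wtp Willingness to pay per QALY for the `"nmb"` rule (default
#'   $100,000).
#' @param lower,upper Search interval for the overall response rate.
#' @param tol Bisection tolerance on the rate.
#' @param scenario,perspective Context evaluated (defaults: base case,
#'   societal).
#' @return A list with `threshold` (the rate, or `NA` if traditional CBT is
#'   never preferred on the interval), `rule`, `wtp` and the comparison at
#'   the threshold (`comparison`, `NULL` when no crossing exists).
#' @export
threshold_search <- function(params, rule = c("nmb", "dominance"), wtp = 1e5,
                             lower = 0.42, upper = 1, tol = 0.001,
                             scenario = "base", perspective = "societal") {
  rule <- match.arg(rule)
  mobile <- mobile_cbt_strategy(params)
  status_quo <- status_quo_strategy()

  outcome_at <- function(strategy) {
    trace <- run_cohort(params, strategy, scenario)
    accumulate(trace, params, strategy, perspective)
  }
  mob_out <- outcome_at(mobile)

  preferred <- function(rate) {
    trad <- traditional_cbt_strategy(params, overall_response = rate)
    trad_out <- outcome_at(trad)
    if (rule == "nmb") {
      nmb_t <- wtp * trad_out$qalys - trad_out$cost_total
      nmb_m <- wtp * mob_out$qalys - mob_out$cost_total
      nmb_t >= nmb_m
    } else {
      trad_out$cost_total < mob_out$cost_total && trad_out$qalys >= mob_out$qalys
    }
  }

  if (preferred(lower)) {
    threshold <- lower
  } else if (!preferred(upper)) {
    return(list(threshold = NA_real_, rule = rule, wtp = wtp, comparison = NULL))
  } else {
    lo <- lower
    hi <- upper
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (preferred(mid)) hi <- mid else lo <- mid
    }
    threshold <- hi
  }
  trad <- traditional_cbt_strategy(params, overall_response = threshold)
  list(
    threshold = threshold, rule = rule, wtp = wtp,
    comparison = compare(outcome_at(trad), mob_out)
  )
}

#' Tornado-style summary over the sweepable parameters
#'
#' Evaluates each parameter at the low and high end of its declared range
#' and records the resulting cost and QALY deltas of mobile CBT against a
#' comparator, for a tornado diagram.
#'
#' @param params A `gad_parameters` object.
#' @param parameters Parameter keys (default: all sweepable parameters).
#' @param comparator `"traditional_cbt"` or `"status_quo"`.
#' @param scenario,perspective Context evaluated.
#' @return A tibble of class `gad_tornado`: `parameter`, `low`, `high`,
#'   `delta_cost_low`, `delta_cost_high`, `delta_qalys_low`,
#'   `delta_qalys_high`, ordered by the cost-delta span.
#' @export
tornado_summary <- function(params,
                            parameters = parameter_ranges(params)$parameter,
                            comparator = "status_quo",
                            scenario = "base", perspective = "societal") {
  ranges <- parameter_ranges(params)
  rows <- lapply(parameters, function(p) {
    i <- match(p, ranges$parameter)
    if (is.na(i)) stop("parameter is not sweepable: ", p, call. = FALSE)
    sw <- one_way_sweep(params, p,
      values = c(ranges$low[i], ranges$high[i]),
      scenario = scenario, perspective = perspective
    )
    sw <- sw[sw$comparator == comparator, ]
    tibble::tibble(
      parameter = p, low = ranges$low[i], high = ranges$high[i],
      delta_cost_low = sw$delta_cost[1], delta_cost_high = sw$delta_cost[2],
      delta_qalys_low = sw$delta_qalys[1], delta_qalys_high = sw$delta_qalys[2]
    )
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(abs(.data$delta_cost_high - .data$delta_cost_low)))
  class(out) <- c("gad_tornado", class(out))
  out
}
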