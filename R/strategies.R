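#' Intervention strategy specifications
#'
#' A strategy bundles the behavioural-transition modification an intervention
#' induces (a full-effect matrix whose `MILD`/`MOD`/`SEV` rows replace the
#' status-quo rows while the effect lasts), its program cost, the number of
#' cycles over which the program cost accrues, and its waning schedule. The
#' effect is fully sustained through `waning_full_effect_cycles` (default 4,
#' i.e. one year including the 3-month program itself) and then declines
#' linearly to nothing at `waning_end_cycle` (default: the model horizon).
#'
#' @param name Strategy label.
#' @param intervention_matrix 7x7 behavioural matrix at full effect, or
#'   `NULL` for no modification (status quo).
#' @param program_cost Per-person program cost in model dollars.
#' @param program_cycles Number of initial cycles in which the program cost
#'   accrues (default 1: a single 3-month program).
#' @param waning_full_effect_cycles Last cycle with full effect.
#' @param waning_end_cycle Cycle at which the effect reaches zero; `NULL`
#'   means the model horizon.
#' @return An object of class `gad_strategy`.
#' @export
new_strategy <- function(name, intervention_matrix = NULL, program_cost = 0,
                         program_cycles = 1L, waning_full_effect_cycles = 4L,
                         waning_end_cycle = NULL) {
  stopifnot(program_cycles >= 0, program_cost >= 0)
  if (!is.null(waning_end_cycle) &&
    waning_full_effect_cycles > waning_end_cycle) {
    stop("waning_full_effect_cycles must not exceed waning_end_cycle",
      call. = FALSE
    )
  }
  if (!is.null(intervention_matrix)) {
    intervention_matrix <- check_behavioural_matrix(
      intervention_matrix, gad_entry_states(),
      paste0("strategy:", name)
    )
  }
  structure(
    list(
      name = name,
      intervention_matrix = intervention_matrix,
      program_cost = program_cost,
      program_cycles = as.integer(program_cycles),
      waning_full_effect_cycles = as.integer(waning_full_effect_cycles),
      waning_end_cycle = if (is.null(waning_end_cycle)) NULL else as.integer(waning_end_cycle)
    ),
    class = "gad_strategy"
  )
}

#' @export
print.gad_strategy <- function(x, ...) {
  cat(sprintf(
    "<gad_strategy> %s: program $%g x %d cycle(s), full effect through cycle %d, waning ends at %s\n",
    x$name, x$program_cost, x$program_cycles, x$waning_full_effect_cycles,
    if (is.null(x$waning_end_cycle)) "horizon" else x$waning_end_cycle
  ))
  invisible(x)
}

#' Build a full-effect intervention matrix from per-state response rates
#'
#' For each treated state the probability of moving one severity state down
#' is set to the state's response rate; the remaining mass is spread over
#' the status-quo row's non-improving destinations (same state, worse state,
#' comorbidity entry) in proportion to their status-quo probabilities.
#'
#' @param params A `gad_parameters` object (supplies the status-quo rows).
#' @param rates Named response probabilities over `MILD`, `MOD`, `SEV`.
#' @return A 7x7 behavioural matrix with only the treated rows populated.
#' @export
intervention_matrix_from_rates <- function(params, rates) {
  stopifnot(all(gad_entry_states() %in% names(rates)))
  if (any(rates < 0 | rates > 1)) {
    stop("response rates must lie in [0, 1]", call. = FALSE)
  }
  states <- gad_states()
  sq <- params$transitions$status_quo
  m <- matrix(0, 7, 7, dimnames = list(states, states))
  for (s in gad_entry_states()) {
    down <- states[match(s, states) - 1L]
    row <- sq[s, ]
    keep <- setdiff(names(row)[row > 0], down)
    r <- rates[[s]]
    m[s, down] <- r
    if (r < 1) {
      m[s, keep] <- (1 - r) * row[keep] / sum(row[keep])
    }
  }
  m
}

#' Per-state response rates implied by an intervention matrix
#' (the probability of moving one severity state down at full effect)
#' @param strategy_or_matrix A `gad_strategy` or a 7x7 behavioural matrix.
#' @return Named numeric vector over `MILD`, `MOD`, `SEV`.
#' @export
strategy_response_rates <- function(strategy_or_matrix) {
  m <- if (inherits(strategy_or_matrix, "gad_strategy")) {
    strategy_or_matrix$intervention_matrix
  } else {
    strategy_or_matrix
  }
  if (is.null(m)) {
    return(setNames(rep(NA_real_, 3), gad_entry_states()))
  }
  states <- gad_states()
  vapply(
    setNames(gad_entry_states(), gad_entry_states()),
    function(s) m[s, states[match(s, states) - 1L]],
    numeric(1)
  )
}

#' The status-quo (no CBT) strategy
#'
#' No transition modification and no program cost; background
#' pharmacotherapy and healthcare utilization continue.
#'
#' @return A `gad_strategy`.
#' @export
status_quo_strategy <- function() {
  new_strategy("status_quo", intervention_matrix = NULL, program_cost = 0,
    program_cycles = 0L)
}

#' The mobile CBT strategy
#'
#' By default uses the packaged full-effect transition rows (built from the
#' pilot's state-specific response structure). Supply `efficacy` (a
#' `gad_efficacy` table from [estimate_efficacy()]) or `rates` to rebuild
#' the rows from pilot data instead.
#'
#' @param params A `gad_parameters` object.
#' @param efficacy Optional `gad_efficacy` table.
#' @param rates Optional named response-rate vector (overrides `efficacy`).
#' @param waning_end_cycle See [new_strategy()].
#' @return A `gad_strategy`.
#' @export
mobile_cbt_strategy <- function(params, efficacy = NULL, rates = NULL,
                                waning_end_cycle = NULL) {
  m <- if (!is.null(rates)) {
    intervention_matrix_from_rates(params, rates)
  } else if (!is.null(efficacy)) {
    intervention_matrix_from_rates(params, response_rates(efficacy))
  } else {
    params$transitions$mobile_cbt
  }
  new_strategy("mobile_cbt",
    intervention_matrix = m,
    program_cost = params$costs$mobile_program,
    waning_end_cycle = waning_end_cycle
  )
}

#' The traditional face-to-face CBT strategy
#'
#' Clinical-trial evidence for traditional CBT reports a single overall
#' response rate (42% by default) rather than state-specific rates. The
#' overall rate is distributed across the severity states by scaling the
#' mobile program's state-specific response structure with a common factor
#' `k` chosen so that the start-distribution-weighted mean response equals
#' `overall_response`, with each scaled rate capped at 1.
#'
#' @param params A `gad_parameters` object.
#' @param overall_response Target overall clinical response rate.
#' @param weights State weights for the overall rate (default: the base-case
#'   starting distribution).
#' @param structure_rates State-specific rate structure to scale (default:
#'   the mobile program's rates).
#' @param waning_end_cycle See [new_strategy()].
#' @return A `gad_strategy`.
#' @export
traditional_cbt_strategy <- function(params, overall_response = 0.42,
                                     weights = params$start_distributions$base,
                                     structure_rates = NULL,
                                     waning_end_cycle = NULL) {
  if (is.null(structure_rates)) {
    structure_rates <- strategy_response_rates(params$transitions$mobile_cbt)
  }
  rates <- scale_response_rates(structure_rates, overall_response, weights)
  new_strategy("traditional_cbt",
    intervention_matrix = intervention_matrix_from_rates(params, rates),
    program_cost = params$costs$cbt_course,
    waning_end_cycle = waning_end_cycle
  )
}

#' Scale state-specific response rates to hit an overall target
#'
#' Finds `k` such that `sum(w * pmin(1, k * r)) == overall`, and returns
#' `pmin(1, k * r)`. Errors if the target is unattainable even with all
#' rates at 1.
#'
#' @param rates Named per-state rates (the structure).
#' @param overall Target weighted-mean response.
#' @param weights Named weights over the same states (normalised internally).
#' @return Named numeric vector of scaled rates.
#' @export
scale_response_rates <- function(rates, overall, weights) {
  states <- gad_entry_states()
  r <- rates[states]
  w <- weights[states] / sum(weights[states])
  if (overall > sum(w) + 1e-12 || overall < 0) {
    stop("overall response target out of attainable range", call. = FALSE)
  }
  f <- function(k) sum(w * pmin(1, k * r)) - overall
  if (all(r == 0)) stop("structure rates are all zero", call. = FALSE)
  k <- uniroot(f, lower = 0, upper = 1 / min(r[r > 0]) + 1, tol = 1e-12)$root
  setNames(pmin(1, k * r), names(r)) # pmin drops the names of `r`
}

#' Default strategy set (mobile CBT, traditional CBT, status quo)
#'
#' @param params A `gad_parameters` object.
#' @param waning_end_cycle Common waning end cycle (default: horizon).
#' @return Named list of `gad_strategy` objects.
#' @export
default_strategies <- function(params, waning_end_cycle = NULL) {
  list(
    mobile_cbt = mobile_cbt_strategy(params, waning_end_cycle = waning_end_cycle),
    traditional_cbt = traditional_cbt_strategy(params, waning_end_cycle = waning_end_cycle),
    status_quo = status_quo_strategy()
  )
}
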