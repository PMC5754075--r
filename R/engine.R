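#' Waning weight of an intervention effect at a cycle
#'
#' The intervention's transition modification is fully sustained (weight 1)
#' through `waning_full_effect_cycles`, then declines linearly to 0 at
#' `waning_end_cycle` and stays 0 thereafter, so that by the end of the
#' waning window the cohort transitions exactly as under status quo.
#'
#' @param cycle Cycle index (0-based).
#' @param strategy A `gad_strategy`.
#' @param horizon Model horizon in cycles (used when the strategy's
#'   `waning_end_cycle` is `NULL`).
#' @return Weight in `[0, 1]`. Vectorised over `cycle`.
#' @export
#' @examples
#' s <- status_quo_strategy()
#' waning_weight(0:10, s, horizon = 8)
waning_weight <- function(cycle, strategy, horizon) {
  full <- strategy$waning_full_effect_cycles
  end <- if (is.null(strategy$waning_end_cycle)) horizon else strategy$waning_end_cycle
  w <- ifelse(
    cycle <= full, 1,
    ifelse(cycle >= end, 0, (end - cycle) / (end - full))
  )
  pmin(pmax(w, 0), 1)
}

#' Transition matrix for one model cycle
#'
#' Builds the cycle's full 7x7 transition matrix in three steps:
#' 1. blend the behavioural matrices, `w * P_intervention + (1 - w) * P_sq`
#'    with `w` the waning weight (`P_intervention` is the status-quo matrix
#'    with the treated rows replaced by the strategy's full-effect rows);
#' 2. at cycle 0, zero all transitions into the comorbidity states and
#'    renormalise the affected rows (comorbidities are unreachable until
#'    after the first cycle);
#' 3. apply mortality: each living row is scaled by `1 - q` and its `DEAD`
#'    entry set to `q`, where `q` is the age-specific 3-month background
#'    death probability, multiplied by the suicide-hazard multiplier in the
#'    states listed in `params$suicide_states` (capped at 1).
#'
#' @param params A `gad_parameters` object.
#' @param strategy A `gad_strategy`.
#' @param cycle Cycle index (0-based).
#' @param age Cohort age in years at the start of the cycle.
#' @return A 7x7 transition matrix with rows summing to 1 within 1e-12.
#' @export
build_cycle_matrix <- function(params, strategy, cycle, age) {
  states <- gad_states()
  sq <- params$transitions$status_quo
  P <- sq
  if (!is.null(strategy$intervention_matrix)) {
    w <- waning_weight(cycle, strategy, params$horizon_cycles)
    Pint <- sq
    Pint[gad_entry_states(), ] <- strategy$intervention_matrix[gad_entry_states(), ]
    # skip the blend when it cannot change anything, so a strategy whose
    # rows equal status quo reproduces status quo exactly
    if (w > 0 && !identical(Pint, sq)) {
      P <- if (w >= 1) Pint else w * Pint + (1 - w) * sq
    }
  }
  if (cycle == 0) {
    # comorbidity states are unreachable until after the first cycle; only
    # non-comorbid rows can carry entry mass at cycle 0 (the comorbid rows
    # are vacuous then, since no one starts there)
    entry_rows <- setdiff(gad_living_states(), gad_comorbidity_states())
    P[entry_rows, gad_comorbidity_states()] <- 0
    rs <- rowSums(P[entry_rows, , drop = FALSE])
    if (any(rs <= 0)) stop("cycle-0 gating emptied a transition row", call. = FALSE)
    P[entry_rows, ] <- P[entry_rows, , drop = FALSE] / rs
  }
  q_bg <- mortality_q(params, age)
  q <- setNames(rep(q_bg, length(gad_living_states())), gad_living_states())
  q[intersect(params$suicide_states, names(q))] <-
    pmin(1, q_bg * params$suicide_multiplier)
  full <- matrix(0, 7, 7, dimnames = list(states, states))
  full[gad_living_states(), ] <-
    P[gad_living_states(), , drop = FALSE] * (1 - q)
  full[gad_living_states(), "DEAD"] <- q
  full["DEAD", "DEAD"] <- 1
  # renormalise to absorb floating-point drift from the blend
  full <- full / rowSums(full)
  if (any(abs(rowSums(full) - 1) > 1e-12)) {
    stop("transition rows are not stochastic", call. = FALSE)
  }
  full
}

#' Propagate the cohort through the model
#'
#' Starts the cohort in the scenario's distribution over the entry states
#' and multiplies the occupancy row vector by the cycle-specific transition
#' matrix for `horizon_cycles` cycles, ageing the cohort 3 months per cycle.
#' Total occupancy (including `DEAD`) is conserved at the cohort size every
#' cycle.
#'
#' @param params A `gad_parameters` object.
#' @param strategy A `gad_strategy`.
#' @param scenario One of `"base"` (prevention and treatment),
#'   `"prevention_only"` (everyone starts mild) or `"treatment_only"`
#'   (everyone starts moderate or severe).
#' @return A tibble of class `gad_trace` with columns `cycle`, `age`,
#'   `state`, `persons` (cycles `0 ... horizon_cycles`); attributes carry
#'   the strategy name, scenario, horizon and cohort size.
#' @export
#' @examples
#' p <- load_default_parameters()
#' tr <- run_cohort(p, status_quo_strategy(), "base")
#' head(tr)
run_cohort <- function(params, strategy,
                       scenario = c("base", "prevention_only", "treatment_only")) {
  scenario <- match.arg(scenario)
  H <- params$horizon_cycles
  if (H < 1) stop("horizon must be at least 1 cycle", call. = FALSE)
  states <- gad_states()
  occ <- matrix(0, H + 1, 7, dimnames = list(NULL, states))
  start <- params$start_distributions[[scenario]]
  occ[1, names(start)] <- params$cohort_size * start
  ages <- params$start_age + params$cycle_length * (0:H)
  for (t in seq_len(H)) {
    M <- build_cycle_matrix(params, strategy, t - 1L, ages[t])
    occ[t + 1, ] <- occ[t, , drop = FALSE] %*% M
  }
  out <- tibble::tibble(
    cycle = rep(0:H, each = 7),
    age = rep(ages, each = 7),
    state = rep(states, H + 1),
    persons = as.vector(t(occ))
  )
  attr(out, "strategy") <- strategy$name
  attr(out, "scenario") <- scenario
  attr(out, "horizon_cycles") <- H
  attr(out, "cohort_size") <- params$cohort_size
  class(out) <- c("gad_trace", class(out))
  out
}

#' Occupancy matrix (cycle x state) of a trace
#' @param trace A `gad_trace`.
#' @return Numeric matrix with one row per cycle (0-based) and one column
#'   per state.
#' @export
trace_occupancy <- function(trace) {
  states <- gad_states()
  H <- attr(trace, "horizon_cycles")
  m <- matrix(trace$persons, H + 1, 7, byrow = TRUE, dimnames = list(NULL, states))
  m
}
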