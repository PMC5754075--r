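#' @importFrom rlang .data
#' @importFrom stats setNames approx uniroot rbinom
#' @importFrom utils modifyList
NULL

gad_extdata <- function(file) {
  path <- system.file("extdata", file, package = "gadcea")
  if (!nzchar(path)) stop("packaged data file not found: ", file, call. = FALSE)
  path
}

# Bounds stated for the 3-month background mortality probability.
MORTALITY_BOUNDS <- c(0.0003, 0.0711)

read_transition_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("context", "from_state", "to_state", "probability")
  if (!all(needed %in% names(raw))) {
    stop("transition file must have columns ", paste(needed, collapse = ", "),
      call. = FALSE
    )
  }
  states <- gad_states()
  bad <- setdiff(unique(c(raw$from_state, raw$to_state)), states)
  if (length(bad) > 0) {
    stop("transitions: unknown state label(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(is.na(raw$probability)) || any(raw$probability < 0)) {
    stop("transitions: probabilities must be present and non-negative",
      call. = FALSE
    )
  }
  out <- lapply(split(raw, raw$context), function(d) {
    m <- matrix(0, 7, 7, dimnames = list(states, states))
    m[cbind(d$from_state, d$to_state)] <- d$probability
    m
  })
  out
}

# Normalise and check a behavioural (pre-mortality) transition matrix.
# `rows`: which rows must be stochastic; others must be all-zero (rows the
# context does not specify, e.g. intervention contexts only replace the rows
# of the states whose members are treated).
check_behavioural_matrix <- function(m, rows, context) {
  if (any(m[gad_living_states(), "DEAD"] != 0) ||
    any(m["DEAD", gad_living_states()] != 0)) {
    stop("transitions[", context, "]: behavioural matrix must not move mass ",
      "to or from DEAD (mortality is applied separately)",
      call. = FALSE
    )
  }
  m["DEAD", ] <- 0 # DEAD handled by the mortality step, not the behavioural matrix
  for (s in rows) {
    rs <- sum(m[s, ])
    if (rs <= 0) {
      stop("transitions[", context, "]: missing row for state ", s, call. = FALSE)
    }
    if (abs(rs - 1) > 1e-6) {
      stop("transitions[", context, "]: row ", s, " sums to ", format(rs),
        ", not 1",
        call. = FALSE
      )
    }
    m[s, ] <- m[s, ] / rs
  }
  other <- setdiff(gad_living_states(), rows)
  if (length(other) > 0 && any(m[other, , drop = FALSE] != 0)) {
    stop("transitions[", context, "]: unexpected rows outside ",
      paste(rows, collapse = ", "),
      call. = FALSE
    )
  }
  m
}

#' Default model parameters
#'
#' Builds the full parameter set used by the cohort model: demographics,
#' severity-state utilities, age-banded baseline (non-GAD) healthcare costs,
#' unit costs, 3-month utilization profiles per state, the age-to-mortality
#' table, and the behavioural transition matrices (status quo, plus the
#' full-effect mobile CBT rows). Transition and utilization values ship as
#' editable packaged CSV files; they are synthetic stand-ins constructed to
#' be consistent with the published cohort-level results, not a transcription
#' of primary data (see the package vignette). All other defaults are the
#' published point estimates.
#'
#' @return An object of class `gad_parameters` (a validated named list).
#' @export
#' @examples
#' p <- load_default_parameters()
#' p$cohort_size
#' p$utilities[["NO_ANX"]]
load_default_parameters <- function() {
  trans <- read_transition_csv(gad_extdata("transitions_synthetic.csv"))
  if (!all(c("status_quo", "mobile_cbt") %in% names(trans))) {
    stop("packaged transitions must provide 'status_quo' and 'mobile_cbt' contexts",
      call. = FALSE
    )
  }
  util <- utils::read.csv(gad_extdata("utilization_synthetic.csv"),
    stringsAsFactors = FALSE
  )
  mort <- utils::read.csv(gad_extdata("mortality_synthetic.csv"))
  base_cost <- utils::read.csv(gad_extdata("baseline_costs_synthetic.csv"))

  params <- structure(
    list(
      cohort_size = 100000,
      start_age = 38,
      cycle_length = 0.25,
      horizon_cycles = 288L,
      discount_rate = 0.03,
      med_fraction = 0.586,
      currency_year = 2016,
      suicide_multiplier = 2.0,
      suicide_states = gad_comorbidity_states(),
      disability_productivity_factor = 1.0,
      start_distributions = list(
        base = c(MILD = 0.323, MOD = 0.446, SEV = 0.231),
        prevention_only = c(MILD = 1, MOD = 0, SEV = 0),
        treatment_only = c(MILD = 0, MOD = 0.659, SEV = 0.341)
      ),
      utilities = c(
        NO_ANX = 0.80, MILD = 0.72, MOD = 0.68, SEV = 0.64,
        MOD_COMORB = 0.56, SEV_COMORB = 0.48, DEAD = 0
      ),
      costs = list(
        cbt_course = 1200,
        mobile_program = 150,
        pharma_3mo = 105,
        physician_visit = 143,
        er_visit = 782,
        hospitalization = 8986,
        disability_day = 206,
        baseline_nongad_annual = base_cost
      ),
      utilization = util,
      mortality_table = mort,
      transitions = trans
    ),
    class = "gad_parameters"
  )
  validate_parameters(params)
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the model inputs and returns the
#' parameter set with transition rows renormalised to machine precision.
#' Violations raise an error naming the offending field.
#'
#' @param params A `gad_parameters` object (or a plain list with the same
#'   fields).
#' @return The validated `gad_parameters` object.
#' @export
validate_parameters <- function(params) {
  chk <- function(cond, field, msg) {
    if (!cond) stop("invalid parameter [", field, "]: ", msg, call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x)

  chk(num1(params$cohort_size) && params$cohort_size > 0, "cohort_size", "must be a positive number")
  chk(num1(params$start_age) && params$start_age >= 18, "start_age", "must be an adult age")
  chk(num1(params$cycle_length) && params$cycle_length > 0, "cycle_length", "must be positive")
  chk(num1(params$horizon_cycles) && params$horizon_cycles >= 1, "horizon_cycles", "must be >= 1")
  chk(num1(params$discount_rate) && params$discount_rate >= 0, "discount_rate", "must be >= 0")
  chk(num1(params$med_fraction) && params$med_fraction >= 0 && params$med_fraction <= 1,
    "med_fraction", "must lie in [0, 1]"
  )
  chk(num1(params$suicide_multiplier) && params$suicide_multiplier >= 0,
    "suicide_multiplier", "must be >= 0"
  )
  chk(
    all(params$suicide_states %in% gad_living_states()),
    "suicide_states", "must be living states"
  )
  chk(
    num1(params$disability_productivity_factor) &&
      params$disability_productivity_factor >= 0 &&
      params$disability_productivity_factor <= 1,
    "disability_productivity_factor", "must lie in [0, 1]"
  )

  for (sc in c("base", "prevention_only", "treatment_only")) {
    d <- params$start_distributions[[sc]]
    chk(!is.null(d) && setequal(names(d), gad_entry_states()),
      paste0("start_distributions.", sc), "must cover MILD, MOD, SEV"
    )
    chk(all(d >= 0) && abs(sum(d) - 1) < 1e-9,
      paste0("start_distributions.", sc), "must be non-negative and sum to 1"
    )
  }

  u <- params$utilities
  chk(setequal(names(u), gad_states()), "utilities", "must cover all 7 states")
  chk(all(u >= 0 & u <= 1), "utilities", "must lie in [0, 1]")
  chk(u[["DEAD"]] == 0, "utilities.DEAD", "must be 0")

  cc <- params$costs
  for (f in c(
    "cbt_course", "mobile_program", "pharma_3mo", "physician_visit",
    "er_visit", "hospitalization", "disability_day"
  )) {
    chk(num1(cc[[f]]) && cc[[f]] >= 0, paste0("costs.", f), "must be a non-negative number")
  }
  bc <- cc$baseline_nongad_annual
  chk(
    is.data.frame(bc) && all(c("age_min", "annual_cost") %in% names(bc)) &&
      !any(is.na(bc)) && all(bc$annual_cost >= 0) && !is.unsorted(bc$age_min),
    "costs.baseline_nongad_annual", "must be an age-banded schedule (age_min, annual_cost)"
  )

  ut <- params$utilization
  chk(
    is.data.frame(ut) && setequal(ut$state, gad_living_states()) &&
      all(c(
        "physician_visits", "er_visits", "hospitalizations",
        "disability_days"
      ) %in% names(ut)),
    "utilization", "must cover all 6 living states with the 4 count columns"
  )
  chk(
    !any(is.na(ut[-1])) && all(as.matrix(ut[-1]) >= 0),
    "utilization", "counts must be present and non-negative"
  )

  mt <- params$mortality_table
  chk(
    is.data.frame(mt) && all(c("age", "q_3month") %in% names(mt)) &&
      !any(is.na(mt)) && !is.unsorted(mt$age),
    "mortality_table", "must be (age, q_3month) with increasing ages"
  )
  chk(
    all(mt$q_3month >= MORTALITY_BOUNDS[1] - 1e-12) &&
      all(mt$q_3month <= MORTALITY_BOUNDS[2] + 1e-12),
    "mortality_table",
    sprintf("q_3month must lie in [%g, %g]", MORTALITY_BOUNDS[1], MORTALITY_BOUNDS[2])
  )

  chk(
    is.list(params$transitions) &&
      all(c("status_quo", "mobile_cbt") %in% names(params$transitions)),
    "transitions", "must provide 'status_quo' and 'mobile_cbt' contexts"
  )
  params$transitions$status_quo <- check_behavioural_matrix(
    params$transitions$status_quo, gad_living_states(), "status_quo"
  )
  for (ctx in setdiff(names(params$transitions), "status_quo")) {
    params$transitions[[ctx]] <- check_behavioural_matrix(
      params$transitions[[ctx]], gad_entry_states(), ctx
    )
  }
  class(params) <- "gad_parameters"
  params
}

#' @export
print.gad_parameters <- function(x, ...) {
  cat("<gad_parameters>\n")
  cat(sprintf(
    "  cohort %s starting at age %g, %d cycles of %.2f y, discount %.1f%%/y\n",
    format(x$cohort_size, big.mark = ","), x$start_age, x$horizon_cycles,
    x$cycle_length, 100 * x$discount_rate
  ))
  cat(
    "  transition contexts:",
    paste(names(x$transitions), collapse = ", "), "\n"
  )
  invisible(x)
}

#' Background 3-month mortality probability at an age
#'
#' Linear interpolation between the tabulated ages, held constant beyond the
#' table and clamped to the stated bounds.
#'
#' @param params A `gad_parameters` object.
#' @param age Age(s) in years.
#' @return Numeric vector of 3-month death probabilities.
#' @export
mortality_q <- function(params, age) {
  mt <- params$mortality_table
  q <- approx(mt$age, mt$q_3month, xout = age, rule = 2)$y
  pmin(pmax(q, MORTALITY_BOUNDS[1]), MORTALITY_BOUNDS[2])
}

#' Baseline (non-GAD) annual healthcare cost at an age
#'
#' Step function over age bands; ages below the first band take the first
#' band's value.
#'
#' @param params A `gad_parameters` object.
#' @param age Age(s) in years.
#' @return Annual cost(s) in model dollars.
#' @export
baseline_annual_cost <- function(params, age) {
  bc <- params$costs$baseline_nongad_annual
  idx <- pmax(findInterval(age, bc$age_min), 1L)
  bc$annual_cost[idx]
}

#' Sensitivity ranges of the sweepable parameters
#'
#' One row per parameter that carries a published (or, for utilization
#' counts and the suicide-hazard multiplier, a +/-20%) range. Parameters
#' without a row are not sweepable.
#'
#' @param params A `gad_parameters` object.
#' @return A tibble with columns `parameter`, `default`, `low`, `high`,
#'   `kind` (`"absolute"` for printed ranges, `"multiplicative"` for +/-20%).
#' @export
parameter_ranges <- function(params) {
  printed <- tibble::tribble(
    ~parameter, ~low, ~high,
    "med_fraction", 0, 1,
    "costs.cbt_course", 960, 1440,
    "costs.mobile_program", 120, 180,
    "costs.pharma_3mo", 84, 126,
    "costs.physician_visit", 115, 172,
    "costs.er_visit", 625, 938,
    "costs.hospitalization", 7189, 10739,
    "costs.disability_day", 165, 247
  )
  printed$kind <- "absolute"
  mult <- c(
    "suicide_multiplier",
    as.vector(outer(
      paste0("utilization.", params$utilization$state),
      c(
        "physician_visits", "er_visits", "hospitalizations",
        "disability_days"
      ),
      paste,
      sep = "."
    ))
  )
  mult_tbl <- tibble::tibble(parameter = mult, low = NA_real_, high = NA_real_,
    kind = "multiplicative")
  out <- dplyr::bind_rows(printed, mult_tbl)
  out$default <- vapply(out$parameter, function(p) param_get(params, p), numeric(1))
  out$low <- ifelse(out$kind == "multiplicative", 0.8 * out$default, out$low)
  out$high <- ifelse(out$kind == "multiplicative", 1.2 * out$default, out$high)
  stopifnot(all(out$low <= out$default & out$default <= out$high))
  dplyr::select(out, "parameter", "default", "low", "high", "kind")
}

split_key <- function(parameter) strsplit(parameter, ".", fixed = TRUE)[[1]]

#' Read a parameter by flat key
#'
#' Keys mirror the parameter table: top-level scalars (`"discount_rate"`),
#' `"costs.<field>"`, `"utilities.<state>"`, and
#' `"utilization.<state>.<column>"`.
#'
#' @param params A `gad_parameters` object.
#' @param parameter Flat key string.
#' @return The numeric value.
#' @export
param_get <- function(params, parameter) {
  kp <- split_key(parameter)
  if (length(kp) == 1) {
    v <- params[[kp]]
    if (!is.numeric(v) || length(v) != 1) {
      stop("unknown or non-scalar parameter: ", parameter, call. = FALSE)
    }
    return(v)
  }
  if (kp[1] == "costs" && length(kp) == 2) {
    v <- params$costs[[kp[2]]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1) {
      stop("unknown parameter: ", parameter, call. = FALSE)
    }
    return(v)
  }
  if (kp[1] == "utilities" && length(kp) == 2 && kp[2] %in% gad_states()) {
    return(params$utilities[[kp[2]]])
  }
  if (kp[1] == "utilization" && length(kp) == 3) {
    i <- match(kp[2], params$utilization$state)
    if (is.na(i) || !kp[3] %in% names(params$utilization)) {
      stop("unknown parameter: ", parameter, call. = FALSE)
    }
    return(params$utilization[[kp[3]]][i])
  }
  stop("unknown parameter: ", parameter, call. = FALSE)
}

#' Set a parameter by flat key
#'
#' @inheritParams param_get
#' @param value New numeric value.
#' @return A new validated `gad_parameters` object; the input is unchanged.
#' @export
param_set <- function(params, parameter, value) {
  param_get(params, parameter) # raises on unknown keys
  kp <- split_key(parameter)
  if (length(kp) == 1) {
    params[[kp]] <- value
  } else if (kp[1] == "costs") {
    params$costs[[kp[2]]] <- value
  } else if (kp[1] == "utilities") {
    params$utilities[[kp[2]]] <- value
  } else {
    i <- match(kp[2], params$utilization$state)
    params$utilization[[kp[3]]][i] <- value
  }
  validate_parameters(params)
}

#' Adjust a cost to the model currency year using a CPI series
#'
#' Scales `amount` by the ratio of the consumer price index in `to_year`
#' (default 2016, the model's currency year) to the index in `from_year`.
#'
#' @param amount Dollar amount(s) expressed in `from_year` dollars.
#' @param from_year Calendar year the amount is expressed in.
#' @param cpi_index A data frame with columns `year` and `index`, or a
#'   numeric vector named by year. Defaults to the packaged annual CPI-U
#'   series.
#' @param to_year Target year (default 2016).
#' @return Amount(s) in `to_year` dollars.
#' @export
#' @examples
#' adjust_to_currency_year(105, 2013)
adjust_to_currency_year <- function(amount, from_year, cpi_index = default_cpi(),
                                    to_year = 2016) {
  if (is.data.frame(cpi_index)) {
    cpi_index <- setNames(cpi_index$index, cpi_index$year)
  }
  idx <- function(y) {
    v <- cpi_index[as.character(y)]
    if (any(is.na(v))) {
      stop("CPI index has no entry for year ", paste(y[is.na(v)], collapse = ", "),
        call. = FALSE
      )
    }
    unname(v)
  }
  amount * idx(to_year) / idx(from_year)
}

#' Packaged annual CPI-U series
#' @return Data frame with columns `year`, `index`.
#' @export
default_cpi <- function() {
  utils::read.csv(gad_extdata("cpi_annual.csv"))
}
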