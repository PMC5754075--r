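#' Simulate paired GAD-7 screens from a CBT pilot program
#'
#' Generates a synthetic pilot dataset: each participant has a baseline
#' GAD-7 score drawn uniformly within the score band of a baseline severity
#' state sampled from `baseline_dist`, and a month-3 score. With probability
#' `response_probs[state]` the participant clinically responds and the
#' month-3 score is drawn uniformly from the band one severity level lower;
#' otherwise it is drawn from the same band, or (with probability
#' `worse_fraction` among non-responders) from the band one level higher.
#' Severe non-responders who would deteriorate stay severe, as there is no
#' higher band.
#'
#' The defaults emulate the pilot the model's case study draws on: 89
#' participants, the base-case severity mix at intake, and a 70% response
#' probability in every state.
#'
#' @param n Number of participants (>= 1).
#' @param baseline_dist Named fractions over `MILD`, `MOD`, `SEV`; must sum
#'   to 1.
#' @param response_probs Named per-state probabilities of moving one severity
#'   state down by month 3.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @param worse_fraction Fraction of non-responders who deteriorate by one
#'   state (default 0: non-responders stay in their band).
#' @return A tibble of class `gad_pilot` with columns `id`, `gad7_baseline`,
#'   `gad7_month3`; the seed is kept in the `"seed"` attribute.
#' @export
#' @examples
#' pilot <- simulate_pilot(n = 89, seed = 42)
#' estimate_efficacy(pilot)
simulate_pilot <- function(n = 89,
                           baseline_dist = c(MILD = 0.323, MOD = 0.446, SEV = 0.231),
                           response_probs = c(MILD = 0.70, MOD = 0.70, SEV = 0.70),
                           seed = 20180104,
                           worse_fraction = 0) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  n <- as.integer(n)
  if (!setequal(names(baseline_dist), gad_entry_states()) ||
    any(baseline_dist < 0) || abs(sum(baseline_dist) - 1) > 1e-9) {
    stop("`baseline_dist` must be fractions over MILD, MOD, SEV summing to 1",
      call. = FALSE
    )
  }
  if (!all(gad_entry_states() %in% names(response_probs)) ||
    any(response_probs < 0) || any(response_probs > 1)) {
    stop("`response_probs` must be probabilities for MILD, MOD, SEV", call. = FALSE)
  }
  if (worse_fraction < 0 || worse_fraction > 1) {
    stop("`worse_fraction` must lie in [0, 1]", call. = FALSE)
  }

  ladder <- c("NO_ANX", "MILD", "MOD", "SEV")
  draw_in_band <- function(state) {
    b <- gad7_band(state)
    sample(seq(b[1], b[2]), 1L)
  }

  # scope the RNG: restore the caller's random state on exit
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)

  base_state <- sample(gad_entry_states(), n,
    replace = TRUE,
    prob = baseline_dist[gad_entry_states()]
  )
  base_score <- vapply(base_state, draw_in_band, integer(1))
  responded <- stats::runif(n) < response_probs[base_state]
  worse <- !responded & stats::runif(n) < worse_fraction
  month3_state <- base_state
  month3_state[responded] <- ladder[match(base_state[responded], ladder) - 1L]
  can_worsen <- worse & base_state != "SEV"
  month3_state[can_worsen] <- ladder[match(base_state[can_worsen], ladder) + 1L]
  month3_score <- vapply(month3_state, draw_in_band, integer(1))

  out <- tibble::tibble(
    id = sprintf("P%04d", seq_len(n)),
    gad7_baseline = base_score,
    gad7_month3 = month3_score
  )
  attr(out, "seed") <- seed
  class(out) <- c("gad_pilot", class(out))
  out
}

#' Estimate clinical response rates from paired GAD-7 screens
#'
#' A participant clinically responds when the month-3 severity state is
#' strictly lower than the baseline state (a score drop within the same band
#' does not count). Rates are estimated per baseline state and pooled;
#' records whose baseline maps to `NO_ANX` cannot respond by this definition
#' and are excluded with a warning.
#'
#' @param data A data frame with integer columns `gad7_baseline` and
#'   `gad7_month3` (e.g. from [simulate_pilot()] or [read_pilot_csv()]).
#' @return An object of class `gad_efficacy`: a tibble with one row per
#'   baseline state (`state`, `responders`, `total`, `response`) plus
#'   attributes `overall` (pooled response rate), `n_used` and `n_excluded`.
#' @export
estimate_efficacy <- function(data) {
  stopifnot(all(c("gad7_baseline", "gad7_month3") %in% names(data)))
  base_state <- gad7_to_state(data$gad7_baseline)
  post_state <- gad7_to_state(data$gad7_month3)
  excl <- base_state == "NO_ANX"
  if (any(excl)) {
    warning(
      sum(excl), " record(s) with baseline state NO_ANX excluded from ",
      "efficacy estimation",
      call. = FALSE
    )
  }
  base_state <- base_state[!excl]
  post_state <- post_state[!excl]
  if (length(base_state) == 0) stop("no usable pilot records", call. = FALSE)
  responded <- severity_rank(post_state) < severity_rank(base_state)

  tab <- tibble::tibble(state = base_state, responded = responded) |>
    dplyr::count(.data$state, wt = NULL, name = "total") |>
    dplyr::left_join(
      tibble::tibble(state = base_state[responded]) |>
        dplyr::count(.data$state, name = "responders"),
      by = "state"
    ) |>
    dplyr::mutate(
      responders = dplyr::coalesce(.data$responders, 0L),
      response = .data$responders / .data$total
    ) |>
    dplyr::arrange(match(.data$state, gad_states())) |>
    dplyr::select("state", "responders", "total", "response")

  attr(tab, "overall") <- sum(tab$responders) / sum(tab$total)
  attr(tab, "n_used") <- length(base_state)
  attr(tab, "n_excluded") <- sum(excl)
  class(tab) <- c("gad_efficacy", class(tab))
  tab
}

#' @export
print.gad_efficacy <- function(x, ...) {
  cat(sprintf(
    "<gad_efficacy>  overall response %.1f%% (%d of %d records)\n",
    100 * attr(x, "overall"), sum(x$responders), sum(x$total)
  ))
  NextMethod()
}

#' Per-state response rates of an efficacy table as a named vector
#'
#' States with no observed participants fall back to `fallback` (default:
#' the pooled rate), so a small pilot still yields a complete rate map.
#'
#' @param efficacy A `gad_efficacy` object.
#' @param fallback Rate used for entry states absent from the table.
#' @return Named numeric vector over `MILD`, `MOD`, `SEV`.
#' @export
response_rates <- function(efficacy, fallback = attr(efficacy, "overall")) {
  r <- setNames(
    rep(fallback, length(gad_entry_states())),
    gad_entry_states()
  )
  hit <- intersect(efficacy$state, names(r))
  r[hit] <- efficacy$response[match(hit, efficacy$state)]
  r
}

#' Read / write pilot datasets as CSV
#'
#' @param path File path.
#' @return `read_pilot_csv()` returns a `gad_pilot` tibble.
#' @export
read_pilot_csv <- function(path) {
  out <- readr::read_csv(path,
    col_types = readr::cols(
      id = readr::col_character(),
      gad7_baseline = readr::col_integer(),
      gad7_month3 = readr::col_integer()
    )
  )
  if (any(out$gad7_baseline < 0 | out$gad7_baseline > 21) ||
    any(out$gad7_month3 < 0 | out$gad7_month3 > 21)) {
    stop("GAD-7 scores must lie in [0, 21]", call. = FALSE)
  }
  class(out) <- c("gad_pilot", class(out))
  out
}

#' @rdname read_pilot_csv
#' @param data A pilot dataset.
#' @export
write_pilot_csv <- function(data, path) {
  readr::write_csv(data[, c("id", "gad7_baseline", "gad7_month3")], path)
  invisible(path)
}
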