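#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an economic outcome into component rows
#'
#' @param x A `gad_outcome`.
#' @param ... Unused.
#' @return A tibble with one row per cost component: `strategy`, `scenario`,
#'   `perspective`, `component`, `cost`.
#' @export
tidy.gad_outcome <- function(x, ...) {
  tibble::tibble(
    strategy = x$strategy, scenario = x$scenario, perspective = x$perspective,
    component = names(x$cost_by_component),
    cost = unname(x$cost_by_component)
  )
}

#' One-row summary of an economic outcome
#'
#' @param x A `gad_outcome`.
#' @param ... Unused.
#' @return A one-row tibble: labels, `cost_total`, `qalys`,
#'   `life_expectancy` (undiscounted per-person years alive), and
#'   `life_years_no_anx`.
#' @export
glance.gad_outcome <- function(x, ...) {
  tibble::tibble(
    strategy = x$strategy, scenario = x$scenario, perspective = x$perspective,
    cost_total = x$cost_total, qalys = x$qalys,
    life_expectancy = sum(x$life_years),
    life_years_no_anx = unname(x$life_years[["NO_ANX"]])
  )
}

#' Tidy a pilot efficacy table
#'
#' @param x A `gad_efficacy`.
#' @param ... Unused.
#' @return The per-state tibble (`state`, `responders`, `total`,
#'   `response`).
#' @export
tidy.gad_efficacy <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a pilot efficacy table
#'
#' @param x A `gad_efficacy`.
#' @param ... Unused.
#' @return A one-row tibble: `overall_response`, `n_used`, `n_excluded`.
#' @export
glance.gad_efficacy <- function(x, ...) {
  tibble::tibble(
    overall_response = attr(x, "overall"),
    n_used = attr(x, "n_used"),
    n_excluded = attr(x, "n_excluded")
  )
}

#' Per-person life-years by state from a grid
#'
#' Convenience accessor: unnests the undiscounted per-person life-years of
#' every outcome in a grid.
#'
#' @param grid A `gad_grid` from [run_all()].
#' @return A tibble: `strategy`, `scenario`, `state`, `years`.
#' @export
life_years_table <- function(grid) {
  grid |>
    dplyr::filter(.data$perspective == .data$perspective[1]) |>
    dplyr::mutate(ly = purrr::map(.data$outcome, function(o) {
      tibble::tibble(state = names(o$life_years), years = unname(o$life_years))
    })) |>
    dplyr::select("strategy", "scenario", "ly") |>
    tidyr::unnest("ly")
}
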