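gad_scenarios <- function() c("base", "prevention_only", "treatment_only")
gad_perspectives <- function() c("societal", "payer")

#' Run the full strategy x scenario x perspective grid
#'
#' Propagates each strategy's cohort once per scenario (the trace does not
#' depend on the perspective) and accumulates economic outcomes under both
#' perspectives. Deterministic given the parameters.
#'
#' @param params A `gad_parameters` object.
#' @param strategies Named list of `gad_strategy` objects (default:
#'   [default_strategies()]).
#' @param scenarios Scenarios to run (default all three).
#' @param perspectives Perspectives to run (default both).
#' @return A tibble of class `gad_grid` with one row per combination:
#'   `strategy`, `scenario`, `perspective`, `cost_total`, `qalys`,
#'   `life_expectancy`, plus an `outcome` list-column of `gad_outcome`
#'   objects.
#' @export
#' @examples
#' \donttest{
#' p <- load_default_parameters()
#' grid <- run_all(p)
#' dplyr::select(grid, strategy, scenario, perspective, cost_total, qalys)
#' }
run_all <- function(params, strategies = default_strategies(params),
                    scenarios = gad_scenarios(),
                    perspectives = gad_perspectives()) {
  if (length(strategies) == 0) stop("`strategies` must be non-empty", call. = FALSE)
  if (is.null(names(strategies))) {
    names(strategies) <- vapply(strategies, `[[`, character(1), "name")
  }
  rows <- list()
  for (sc in scenarios) {
    for (nm in names(strategies)) {
      trace <- run_cohort(params, strategies[[nm]], sc)
      for (pv in perspectives) {
        oc <- accumulate(trace, params, strategies[[nm]], pv)
        oc$strategy <- nm # honour the caller's labels (lists may repeat a spec)
        rows[[length(rows) + 1]] <- tibble::tibble(
          strategy = nm, scenario = sc, perspective = pv,
          cost_total = oc$cost_total, qalys = oc$qalys,
          life_expectancy = sum(oc$life_years),
          outcome = list(oc)
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("gad_grid", class(out))
  out
}

grid_outcome <- function(grid, strategy, scenario, perspective) {
  i <- which(grid$strategy == strategy & grid$scenario == scenario &
    grid$perspective == perspective)
  if (length(i) != 1) {
    stop("grid is missing cell: ", strategy, " / ", scenario, " / ", perspective,
      call. = FALSE
    )
  }
  grid$outcome[[i]]
}

#' Compare two economic outcomes
#'
#' Uses the savings convention: `delta_cost = cost(comparator) - cost(a)` is
#' positive when the candidate `a` reduces costs, and
#' `delta_qalys = qalys(a) - qalys(comparator)` is positive when it adds
#' QALYs. The candidate is `cost_saving` (dominant) when both deltas are
#' positive and `dominated` when both are negative; when the signs disagree
#' an incremental cost-effectiveness ratio (cost per QALY gained) is
#' reported instead.
#'
#' @param a The candidate `gad_outcome`.
#' @param b The comparator `gad_outcome`; must share scenario and
#'   perspective with `a`.
#' @return A one-row tibble: `reference`, `comparator`, `scenario`,
#'   `perspective`, `delta_cost`, `delta_qalys`, `verdict`, `icer`.
#' @export
compare <- function(a, b) {
  if (a$scenario != b$scenario || a$perspective != b$perspective) {
    stop("outcomes must share scenario and perspective to be compared",
      call. = FALSE
    )
  }
  delta_cost <- b$cost_total - a$cost_total
  delta_qalys <- a$qalys - b$qalys
  if (delta_cost > 0 && delta_qalys >= 0) {
    verdict <- "cost_saving"
    icer <- NA_real_
  } else if (delta_cost < 0 && delta_qalys <= 0) {
    verdict <- "dominated"
    icer <- NA_real_
  } else if (delta_cost == 0 && delta_qalys == 0) {
    verdict <- "equivalent"
    icer <- NA_real_
  } else {
    verdict <- "icer"
    icer <- -delta_cost / delta_qalys
  }
  tibble::tibble(
    reference = a$strategy, comparator = b$strategy,
    scenario = a$scenario, perspective = a$perspective,
    delta_cost = delta_cost, delta_qalys = delta_qalys,
    verdict = verdict, icer = icer
  )
}

#' Pairwise comparisons of the mobile program against its comparators
#'
#' @param grid A `gad_grid` from [run_all()].
#' @param reference Candidate strategy label (default `"mobile_cbt"`).
#' @param comparators Comparator labels present in the grid.
#' @return Tibble of comparison rows (one per comparator x scenario x
#'   perspective present in the grid).
#' @export
compare_grid <- function(grid, reference = "mobile_cbt",
                         comparators = setdiff(unique(grid$strategy), reference)) {
  cells <- dplyr::distinct(grid, .data$scenario, .data$perspective)
  out <- list()
  for (i in seq_len(nrow(cells))) {
    a <- grid_outcome(grid, reference, cells$scenario[i], cells$perspective[i])
    for (cmp in comparators) {
      b <- grid_outcome(grid, cmp, cells$scenario[i], cells$perspective[i])
      out[[length(out) + 1]] <- compare(a, b)
    }
  }
  dplyr::bind_rows(out)
}

#' Report tables in the published layout
#'
#' Produces the three headline tables from a full grid:
#' * `reductions` — reduction in costs (million dollars) and improvement in
#'   QALYs for mobile CBT vs traditional CBT and vs status quo, per
#'   perspective and scenario;
#' * `life_years` — cumulative undiscounted per-person life-years in each
#'   living state per strategy and scenario (2 decimal places);
#' * `totals` — total discounted lifetime cost per strategy, perspective and
#'   scenario (billion dollars, 1 decimal place).
#'
#' Comparisons are computed at full precision; rounding happens only here,
#' at the reporting layer.
#'
#' @param grid A complete `gad_grid` over the three default strategies,
#'   three scenarios and both perspectives.
#' @return A named list of tibbles (`reductions`, `life_years`, `totals`)
#'   of class `gad_report`.
#' @export
report_tables <- function(grid) {
  needed <- expand.grid(
    strategy = c("mobile_cbt", "traditional_cbt", "status_quo"),
    scenario = gad_scenarios(), perspective = gad_perspectives(),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(needed))) {
    grid_outcome(grid, needed$strategy[i], needed$scenario[i], needed$perspective[i])
  }

  cmp <- compare_grid(grid,
    reference = "mobile_cbt",
    comparators = c("traditional_cbt", "status_quo")
  )
  reductions <- cmp |>
    dplyr::transmute(
      perspective = .data$perspective,
      scenario = .data$scenario,
      comparator = .data$comparator,
      cost_reduction_million = round(.data$delta_cost / 1e6),
      qaly_improvement = round(.data$delta_qalys)
    ) |>
    dplyr::arrange(
      match(.data$perspective, gad_perspectives()),
      match(.data$scenario, gad_scenarios()),
      dplyr::desc(.data$comparator)
    )

  life_years <- grid |>
    dplyr::filter(.data$perspective == "societal") |>
    dplyr::mutate(ly = purrr::map(.data$outcome, function(o) {
      tibble::tibble(state = names(o$life_years), years = round(unname(o$life_years), 2))
    })) |>
    dplyr::select("strategy", "scenario", "ly") |>
    tidyr::unnest("ly") |>
    tidyr::pivot_wider(names_from = "strategy", values_from = "years") |>
    dplyr::arrange(
      match(.data$scenario, gad_scenarios()),
      match(.data$state, gad_states())
    )

  totals <- grid |>
    dplyr::transmute(
      perspective = .data$perspective,
      scenario = .data$scenario,
      strategy = .data$strategy,
      total_cost_billion = round(.data$cost_total / 1e9, 1)
    ) |>
    tidyr::pivot_wider(names_from = "strategy", values_from = "total_cost_billion") |>
    dplyr::arrange(
      match(.data$perspective, gad_perspectives()),
      match(.data$scenario, gad_scenarios())
    )

  structure(
    list(reductions = reductions, life_years = life_years, totals = totals),
    class = "gad_report"
  )
}

#' Write report tables as CSV files
#'
#' One file per table: `table_reductions.csv`, `table_life_years.csv`,
#' `table_totals.csv`.
#'
#' @param report A `gad_report` from [report_tables()].
#' @param dir Output directory (created if missing).
#' @return Paths of the written files, invisibly.
#' @export
write_report_tables <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    reductions = file.path(dir, "table_reductions.csv"),
    life_years = file.path(dir, "table_life_years.csv"),
    totals = file.path(dir, "table_totals.csv")
  )
  for (nm in names(paths)) readr::write_csv(report[[nm]], paths[[nm]])
  invisible(paths)
}
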