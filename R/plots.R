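#' @importFrom ggplot2 autoplot ggplot aes geom_area geom_line geom_point
#'   geom_segment geom_hline labs facet_wrap scale_y_continuous
#'   scale_fill_brewer theme_minimal
#' @export
ggplot2::autoplot

#' Plot a cohort trace
#'
#' Stacked state occupancy of the cohort over age.
#'
#' @param object A `gad_trace` from [run_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gad_trace <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$state <- factor(df$state, levels = rev(gad_states()))
  ggplot(df, aes(x = .data$age, y = .data$persons, fill = .data$state)) +
    geom_area() +
    scale_fill_brewer(palette = "RdYlBu", direction = -1) +
    labs(
      x = "Age (years)", y = "Persons",
      title = paste0(
        "Cohort occupancy: ", attr(object, "strategy"),
        " (", attr(object, "scenario"), ")"
      ),
      fill = "State"
    ) +
    theme_minimal()
}

#' Plot a one-way sweep
#'
#' Cost and QALY deltas of mobile CBT against each comparator across the
#' swept values.
#'
#' @param object A `gad_sweep` from [one_way_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gad_sweep <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot(df, aes(
    x = .data$value, y = .data$delta_cost / 1e6,
    colour = .data$comparator
  )) +
    geom_line() +
    geom_point() +
    geom_hline(yintercept = 0, linetype = "dashed") +
    labs(
      x = df$parameter[1], y = "Cost reduction (million $)",
      title = paste0("One-way sweep: ", df$parameter[1]),
      colour = "Mobile CBT vs"
    ) +
    theme_minimal()
}

#' Tornado diagram of parameter influence
#'
#' Horizontal bars spanning the cost delta obtained at each parameter's low
#' and high range end.
#'
#' @param object A `gad_tornado` from [tornado_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gad_tornado <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot(df, aes(y = .data$parameter)) +
    geom_segment(
      aes(
        x = .data$delta_cost_low / 1e6, xend = .data$delta_cost_high / 1e6,
        yend = .data$parameter
      ),
      linewidth = 4, colour = "steelblue"
    ) +
    labs(
      x = "Cost reduction, mobile CBT vs comparator (million $)",
      y = NULL, title = "One-way sensitivity (tornado)"
    ) +
    theme_minimal()
}
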