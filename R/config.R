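# YAML configuration: a flat, human-editable mirror of the parameter set.
# Every key is optional; anything not given keeps its default. Table-valued
# fields (utilization, mortality_table, baseline schedule, transition
# contexts) are replaced wholesale when present.

config_scalar_keys <- function() {
  c(
    "cohort_size", "start_age", "cycle_length", "horizon_cycles",
    "discount_rate", "med_fraction", "currency_year", "suicide_multiplier",
    "disability_productivity_factor"
  )
}

config_known_keys <- function() {
  c(
    config_scalar_keys(), "suicide_states", "start_distributions",
    "utilities", "costs", "utilization", "mortality_table", "transitions"
  )
}

#' Load parameters from a YAML config file
#'
#' Starts from [load_default_parameters()] and applies the overrides in the
#' file field-wise. Unknown keys, malformed tables and values that break a
#' model invariant (e.g. a transition row that does not sum to 1) raise an
#' error naming the field. An empty file yields the defaults.
#'
#' @param path Path to a YAML file.
#' @param base Parameter set to override (default: the packaged defaults).
#' @return A validated `gad_parameters` object.
#' @export
load_from_config <- function(path, base = load_default_parameters()) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) {
    return(base)
  }
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  apply_config_overrides(base, cfg)
}

#' Apply a list of config-style overrides to a parameter set
#'
#' @param params A `gad_parameters` object.
#' @param cfg Named list in the config schema.
#' @return A validated `gad_parameters` object.
#' @export
apply_config_overrides <- function(params, cfg) {
  unknown <- setdiff(names(cfg), config_known_keys())
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (k in intersect(names(cfg), config_scalar_keys())) {
    params[[k]] <- cfg[[k]]
  }
  if (!is.null(cfg$suicide_states)) {
    params$suicide_states <- as.character(unlist(cfg$suicide_states))
  }
  if (!is.null(cfg$start_distributions)) {
    for (sc in names(cfg$start_distributions)) {
      if (!sc %in% names(params$start_distributions)) {
        stop("unknown config key(s): start_distributions.", sc, call. = FALSE)
      }
      params$start_distributions[[sc]] <- unlist(cfg$start_distributions[[sc]])
    }
  }
  if (!is.null(cfg$utilities)) {
    bad <- setdiff(names(cfg$utilities), gad_states())
    if (length(bad) > 0) {
      stop("unknown config key(s): utilities.", paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    params$utilities[names(cfg$utilities)] <- unlist(cfg$utilities)
  }
  if (!is.null(cfg$costs)) {
    for (k in names(cfg$costs)) {
      if (k == "baseline_nongad_annual") {
        params$costs$baseline_nongad_annual <-
          records_to_df(cfg$costs[[k]], c("age_min", "annual_cost"), "costs.baseline_nongad_annual")
      } else if (k %in% names(params$costs)) {
        params$costs[[k]] <- cfg$costs[[k]]
      } else {
        stop("unknown config key(s): costs.", k, call. = FALSE)
      }
    }
  }
  if (!is.null(cfg$utilization)) {
    params$utilization <- records_to_df(
      cfg$utilization,
      c(
        "state", "physician_visits", "er_visits", "hospitalizations",
        "disability_days"
      ), "utilization"
    )
  }
  if (!is.null(cfg$mortality_table)) {
    params$mortality_table <- records_to_df(
      cfg$mortality_table, c("age", "q_3month"), "mortality_table"
    )
  }
  if (!is.null(cfg$transitions)) {
    states <- gad_states()
    for (ctx in names(cfg$transitions)) {
      # row-wise merge: only the rows named in the config are replaced
      m <- params$transitions[[ctx]]
      if (is.null(m)) m <- matrix(0, 7, 7, dimnames = list(states, states))
      for (from in names(cfg$transitions[[ctx]])) {
        if (!from %in% states) {
          stop("transitions[", ctx, "]: unknown state ", from, call. = FALSE)
        }
        row <- unlist(cfg$transitions[[ctx]][[from]])
        if (!all(names(row) %in% states)) {
          stop("transitions[", ctx, "]: unknown state ",
            paste(setdiff(names(row), states), collapse = ", "),
            call. = FALSE
          )
        }
        m[from, ] <- 0
        m[from, names(row)] <- row
      }
      params$transitions[[ctx]] <- m
    }
  }
  validate_parameters(params)
}

records_to_df <- function(x, cols, field) {
  df <- tryCatch(
    do.call(rbind.data.frame, c(x, list(stringsAsFactors = FALSE))),
    error = function(e) NULL
  )
  if (is.null(df) || !all(cols %in% names(df))) {
    stop("invalid parameter [", field, "]: expected records with fields ",
      paste(cols, collapse = ", "),
      call. = FALSE
    )
  }
  df[cols]
}

#' Serialize a parameter set to the config schema
#'
#' The result round-trips: writing it with [write_parameter_config()] and
#' reading it back with [load_from_config()] reproduces every field.
#'
#' @param params A `gad_parameters` object.
#' @return A named list in the config schema.
#' @export
as_parameter_config <- function(params) {
  mat_to_cfg <- function(m) {
    rows <- rownames(m)[rowSums(m) > 0]
    setNames(lapply(rows, function(from) {
      nz <- m[from, ][m[from, ] > 0]
      as.list(nz)
    }), rows)
  }
  c(
    setNames(lapply(config_scalar_keys(), function(k) params[[k]]), config_scalar_keys()),
    list(
      suicide_states = as.list(params$suicide_states),
      start_distributions = lapply(params$start_distributions, as.list),
      utilities = as.list(params$utilities),
      costs = c(
        params$costs[setdiff(names(params$costs), "baseline_nongad_annual")],
        list(baseline_nongad_annual = df_to_records(params$costs$baseline_nongad_annual))
      ),
      utilization = df_to_records(params$utilization),
      mortality_table = df_to_records(params$mortality_table),
      transitions = lapply(params$transitions, mat_to_cfg)
    )
  )
}

df_to_records <- function(df) {
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

#' Write a parameter set as a YAML config file
#'
#' @param params A `gad_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameter_config <- function(params, path) {
  yaml::write_yaml(as_parameter_config(params), path, precision = 15)
  invisible(path)
}
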