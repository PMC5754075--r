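# Shared fixtures. `default_params()` caches the packaged defaults; the toy
# builders construct small, fully hand-controlled model inputs so tests can
# check arithmetic against closed forms.

default_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_default_parameters()
    cache
  }
})

# A parameter set whose behavioural matrix keeps everyone in their state and
# whose mortality is a constant q at every age: survival is geometric, so
# life-years have a closed form.
flat_params <- function(q = 0.01, horizon = 40L, utilities = NULL) {
  p <- default_params()
  states <- gad_states()
  m <- matrix(0, 7, 7, dimnames = list(states, states))
  diag(m) <- 1
  m["DEAD", ] <- 0
  p$transitions$status_quo <- m
  p$transitions$mobile_cbt <- m[c("MILD", "MOD", "SEV"), , drop = FALSE] |>
    (\(x) {
      full <- matrix(0, 7, 7, dimnames = list(states, states))
      full[rownames(x), ] <- x
      full
    })()
  p$mortality_table <- data.frame(age = c(38, 120), q_3month = c(q, q))
  p$horizon_cycles <- as.integer(horizon)
  p$suicide_multiplier <- 1
  if (!is.null(utilities)) p$utilities <- utilities
  validate_parameters(p)
}

# Zero out every cost so only structure is exercised.
zero_cost_params <- function(p = default_params()) {
  for (f in c(
    "cbt_course", "mobile_program", "pharma_3mo", "physician_visit",
    "er_visit", "hospitalization", "disability_day"
  )) {
    p$costs[[f]] <- 0
  }
  p$costs$baseline_nongad_annual$annual_cost[] <- 0
  validate_parameters(p)
}

# A small random behavioural matrix over the 7 states (no comorbidity entry
# so the cycle-0 gate is inert and the chain is time-homogeneous).
random_behavioural_matrix <- function(allow_comorbidity = TRUE) {
  states <- gad_states()
  m <- matrix(0, 7, 7, dimnames = list(states, states))
  for (s in gad_living_states()) {
    cols <- gad_living_states()
    if (!allow_comorbidity) cols <- setdiff(cols, gad_comorbidity_states())
    if (s %in% gad_comorbidity_states() && !allow_comorbidity) {
      m[s, s] <- 1
      next
    }
    w <- stats::runif(length(cols))
    m[s, cols] <- w / sum(w)
  }
  m
}

expect_stochastic <- function(m, tol = 1e-12) {
  expect_true(all(abs(rowSums(m) - 1) < tol))
  expect_true(all(m >= 0))
}
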