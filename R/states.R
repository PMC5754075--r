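#' Health states of the GAD Markov model
#'
#' The model tracks seven mutually exclusive health states: four anxiety
#' severity levels defined by GAD-7 cut-off scores, two comorbidity states
#' (moderate or severe anxiety with major depressive disorder and/or
#' substance abuse), and death. Comorbidity states are only reachable after
#' the first model cycle; `DEAD` is absorbing.
#'
#' @return Character vector of the seven state labels, in severity order
#'   (`NO_ANX`, `MILD`, `MOD`, `SEV`, `MOD_COMORB`, `SEV_COMORB`, `DEAD`).
#' @export
#' @examples
#' gad_states()
gad_states <- function() {
  c("NO_ANX", "MILD", "MOD", "SEV", "MOD_COMORB", "SEV_COMORB", "DEAD")
}

#' States a cohort member can occupy at model entry
#' @noRd
gad_entry_states <- function() c("MILD", "MOD", "SEV")

#' Living states, in severity order
#' @noRd
gad_living_states <- function() setdiff(gad_states(), "DEAD")

#' Comorbidity states (gated until after the first cycle)
#' @noRd
gad_comorbidity_states <- function() c("MOD_COMORB", "SEV_COMORB")

#' Map a GAD-7 score to a model health state
#'
#' Uses the instrument's standard severity bands: 0-4 no anxiety, 5-9 mild,
#' 10-14 moderate, 15-21 severe. Scores of 10 or above indicate likely
#' clinically diagnosable GAD.
#'
#' @param score Integer GAD-7 score(s) in `[0, 21]`. Vectorised.
#' @return Character vector of state labels (`NO_ANX`, `MILD`, `MOD`, `SEV`).
#' @export
#' @examples
#' gad7_to_state(c(3, 9, 12, 17))
gad7_to_state <- function(score) {
  if (!is.numeric(score) || any(is.na(score)) || any(score != floor(score))) {
    stop("`score` must be integer GAD-7 scores", call. = FALSE)
  }
  if (any(score < 0 | score > 21)) {
    stop("GAD-7 scores must lie in [0, 21]", call. = FALSE)
  }
  state <- character(length(score))
  state[score <= 4] <- "NO_ANX"
  state[score >= 5 & score <= 9] <- "MILD"
  state[score >= 10 & score <= 14] <- "MOD"
  state[score >= 15] <- "SEV"
  state
}

#' GAD-7 score band for a severity state
#' @noRd
gad7_band <- function(state) {
  switch(state,
    NO_ANX = c(0L, 4L),
    MILD   = c(5L, 9L),
    MOD    = c(10L, 14L),
    SEV    = c(15L, 21L),
    stop("no GAD-7 band for state ", state, call. = FALSE)
  )
}

#' Severity rank of a state (1 = no anxiety ... 4 = severe); comorbidity and
#' death have no rank.
#' @noRd
severity_rank <- function(state) {
  match(state, c("NO_ANX", "MILD", "MOD", "SEV"))
}
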