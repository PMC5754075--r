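# Regenerates the packaged synthetic supplement stand-ins under inst/extdata/.
#
# The status-quo transition probabilities and the mortality table carry the
# frozen output of tools/calibrate_transitions.R (12 behavioural
# probabilities plus a mortality scale fitted once so that the no-CBT cohort
# reproduces the published status-quo life-year profile and the published
# status-quo cost totals anchor the utilization scale). The mobile CBT rows
# are rebuilt from the 70% pilot response structure against those status-quo
# rows.

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

states <- c("NO_ANX", "MILD", "MOD", "SEV", "MOD_COMORB", "SEV_COMORB", "DEAD")

# calibrated status-quo behavioural probabilities (off-diagonal moves)
sq_moves <- rbind(
  c("NO_ANX", "MILD", 0.0582),
  c("MILD", "NO_ANX", 0.1120),
  c("MILD", "MOD", 0.0327),
  c("MOD", "MILD", 0.1920),
  c("MOD", "SEV", 0.1028),
  c("MOD", "MOD_COMORB", 0.0283),
  c("SEV", "MOD", 0.0584),
  c("SEV", "SEV_COMORB", 0.0404),
  c("MOD_COMORB", "MOD", 0.1309),
  c("MOD_COMORB", "SEV_COMORB", 0.0977),
  c("SEV_COMORB", "SEV", 0.0654),
  c("SEV_COMORB", "MOD_COMORB", 0.0412)
)

sq <- matrix(0, 7, 7, dimnames = list(states, states))
sq[cbind(sq_moves[, 1], sq_moves[, 2])] <- as.numeric(sq_moves[, 3])
diag(sq) <- 1 - rowSums(sq)
sq["DEAD", ] <- 0
sq["DEAD", "DEAD"] <- 1

# Mobile CBT full-effect rows: 70% response (one state down), remaining mass
# spread over the status-quo row's non-improving entries.
intervention_row <- function(sq, state, r) {
  down <- states[match(state, states) - 1L]
  row <- sq[state, ]
  keep <- setdiff(names(row)[row > 0], down)
  out <- stats::setNames(numeric(7), states)
  out[down] <- r
  out[keep] <- (1 - r) * row[keep] / sum(row[keep])
  out
}

mob <- do.call(rbind, lapply(c("MILD", "MOD", "SEV"), function(s) {
  intervention_row(sq, s, 0.70)
}))
rownames(mob) <- c("MILD", "MOD", "SEV")

to_long <- function(m, context) {
  idx <- which(m > 0, arr.ind = TRUE)
  d <- data.frame(
    context = context,
    from_state = rownames(m)[idx[, 1]],
    to_state = colnames(m)[idx[, 2]],
    probability = m[idx],
    stringsAsFactors = FALSE
  )
  d[order(match(d$from_state, states), match(d$to_state, states)), ]
}

trans <- rbind(to_long(mob, "mobile_cbt"), to_long(sq, "status_quo"))
write.csv(trans, "inst/extdata/transitions_synthetic.csv", row.names = FALSE)

# 3-month anxiety-attributable utilization by state; levels anchored so that
# the no-CBT cohort's discounted lifetime payer total and disability-day
# total match the published status-quo cost totals.
util <- data.frame(
  state = c("NO_ANX", "MILD", "MOD", "SEV", "MOD_COMORB", "SEV_COMORB"),
  physician_visits = c(3.6, 5.5, 9.0, 14.5, 20.0, 25.5),
  er_visits = c(0.07, 0.15, 0.36, 0.65, 0.91, 1.45),
  hospitalizations = c(0.018, 0.036, 0.11, 0.22, 0.36, 0.65),
  disability_days = c(1, 4, 11, 22, 30, 45)
)
write.csv(util, "inst/extdata/utilization_synthetic.csv", row.names = FALSE)

# 3-month background mortality: plausible adult life-table shape, scaled by
# the calibrated factor 1.206 and clamped to the stated bounds.
base_q <- c(0.0003, 0.0005, 0.0008, 0.00125, 0.0019, 0.0030, 0.0045,
            0.0071, 0.0117, 0.0198, 0.0342, 0.0543, 0.0711, 0.0711)
mort <- data.frame(
  age = c(38, 45, 50, 55, 60, 65, 70, 75, 80, 85, 90, 95, 100, 110),
  q_3month = round(pmin(pmax(base_q * 1.206, 0.0003), 0.0711), 5)
)
write.csv(mort, "inst/extdata/mortality_synthetic.csv", row.names = FALSE)

base_cost <- data.frame(
  age_min = c(0, 45, 55, 65, 75),
  annual_cost = c(946, 1654, 2608, 3790, 5154)
)
write.csv(base_cost, "inst/extdata/baseline_costs_synthetic.csv", row.names = FALSE)

# CPI-U annual averages (U.S. Bureau of Labor Statistics, all urban consumers).
cpi <- data.frame(
  year = 2010:2016,
  index = c(218.056, 224.939, 229.594, 232.957, 236.736, 237.017, 240.007)
)
write.csv(cpi, "inst/extdata/cpi_annual.csv", row.names = FALSE)

cat("extdata written\n")
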