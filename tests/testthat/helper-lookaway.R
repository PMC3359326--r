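# Shared fixtures, all built in code.

# A tiny fully-specified design: 3 three-box trials with hand-picked
# sequences, for deterministic covariate checks.
toy_exp2_design <- function() {
  tibble::tibble(
    trial_id = 1:3,
    experiment = 2L,
    p_A = c(1, 0.5, 1 / 3), p_B = c(0, 0.3, 1 / 3), p_C = c(0, 0.2, 1 / 3),
    event_duration_s = 2,
    events = list(
      rep("A", 6),
      c("A", "B", "A", "B", "A", "C"),
      c("C", "B", "B", "A", "C", "A")
    )
  )
}

# Hand-written look-away records exercising every outcome type.
toy_records <- function() {
  tibble::tibble(
    infant_id = 1L,
    trial_id = 1:4,
    trial_number = 1:4,
    lookaway_position = c(NA, NA, 3L, 4L),
    outcome = c("timeout", "false_stop", "lookaway", "lookaway"),
    n_events_observed = c(30L, 7L, 3L, 4L)
  )
}

# Constant-hazard generator params (no complexity, fatigue or tracker
# effects) for null-calibration style checks.
flat_params <- function(h = 0.1, ...) {
  hazard_params(
    baseline_logodds = qlogis(h), curvature = 0, linear = 0,
    trial_slope = 0, false_stop_prob = 0, ...
  )
}

# Small simulated Exp 2 cohort reused across test files.
small_cohort <- function(n_infants = 20, mode = "marginal", seed = 42,
                         params = hazard_params()) {
  design <- generate_exp2_session(seed = seed)
  records <- simulate_cohort(design, n_infants = n_infants, mode = mode,
                             params = params, seed = seed + 1)
  list(design = design, records = records)
}
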