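#' Parameters of the U-shaped look-away hazard
#'
#' The synthetic infant decides at each event whether to stop attending. The
#' linear predictor for the per-event stopping decision is
#'
#' `eta_t = baseline_logodds + curvature * (x_t - optimum)^2 +
#'          linear * (x_t - optimum) + trial_slope * trial_number`
#'
#' where `x_t` is the event's complexity. With `curvature > 0` the hazard is
#' U-shaped in complexity with its minimum at `optimum`; `linear` tilts the U
#' (the observed U is not symmetric); `trial_slope` captures fatigue across
#' the session. Independently of the infant's decision, the eye-tracker can
#' fail at any event (`false_stop_prob`), truncating the trial, and a trial
#' that survives `timeout_events` events times out.
#'
#' Defaults were calibrated once against the reported session statistics:
#' roughly a fifth of trials lost to tracker false stops, a few percent to
#' timeouts, a hazard minimum at 1.25 bits, and a quadratic effect whose
#' fitted standardized Cox coefficient lands in the 0.27-0.36 range.
#'
#' @param baseline_logodds Per-event stopping log-odds at the hazard minimum.
#' @param curvature Quadratic gain (per squared complexity unit); >= 0.
#' @param optimum Hazard-minimizing complexity. In bits when
#'   `standardize = FALSE`, in standard-deviation units otherwise.
#' @param linear Linear (asymmetry) term; 0 gives a symmetric U.
#' @param trial_slope Additive log-odds increment per presented trial
#'   (fatigue).
#' @param false_stop_prob Per-event probability of a tracker false stop, in
#'   `[0, 1)`.
#' @param timeout_events Event cap per trial (60 s timeout at 2 s per event
#'   gives 30).
#' @param link `"logistic"`: per-event stopping probability is
#'   `plogis(eta_t)`. `"cloglog"`: `1 - exp(-exp(eta_t))`, the grouped
#'   proportional-hazards link, under which `eta_t`'s coefficients are on the
#'   same scale as Cox log-hazard coefficients.
#' @param standardize If `TRUE`, `x_t` is the complexity standardized (mean
#'   0, population sd 1) over all events of the session's traces, so
#'   `curvature` is a coefficient on squared standardized complexity.
#' @return A `hazard_params` object (a validated list).
#' @export
hazard_params <- function(baseline_logodds = -3.5,
                          curvature = 1.8,
                          optimum = 1.25,
                          linear = -0.15,
                          trial_slope = 0.028,
                          false_stop_prob = 0.028,
                          timeout_events = 30L,
                          link = c("logistic", "cloglog"),
                          standardize = FALSE) {
  link <- match.arg(link)
  if (curvature < 0) abort("`curvature` must be >= 0.")
  if (false_stop_prob < 0 || false_stop_prob >= 1) {
    abort("`false_stop_prob` must lie in [0, 1).")
  }
  timeout_events <- check_count(timeout_events, "timeout_events")
  structure(
    list(
      baseline_logodds = baseline_logodds, curvature = curvature,
      optimum = optimum, linear = linear, trial_slope = trial_slope,
      false_stop_prob = false_stop_prob, timeout_events = timeout_events,
      link = link, standardize = standardize
    ),
    class = "hazard_params"
  )
}

#' @export
print.hazard_params <- function(x, ...) {
  cat("<hazard_params>\n")
  cat(sprintf(
    "  eta = %.3g + %.3g*(x - %.3g)^2 + %.3g*(x - %.3g) + %.3g*trial\n",
    x$baseline_logodds, x$curvature, x$optimum, x$linear, x$optimum,
    x$trial_slope
  ))
  cat(sprintf(
    "  link = %s, x = %s complexity, false stop %.3g/event, timeout %d events\n",
    x$link, if (x$standardize) "standardized" else "bits", x$false_stop_prob,
    x$timeout_events
  ))
  invisible(x)
}

hazard_prob <- function(eta, link) {
  if (link == "logistic") plogis(eta) else -expm1(-exp(eta))
}

# Core sampler: stopping-probability matrix (records x events) -> outcomes.
# A tracker false stop and a look-away at the same event resolve to a false
# stop (the tracker ended the trial before the look-away registered).
simulate_records <- function(p_look, false_stop_prob) {
  n <- nrow(p_look)
  t_max <- ncol(p_look)
  u_look <- matrix(runif(n * t_max), n, t_max)
  u_fs <- matrix(runif(n * t_max), n, t_max)
  fs_hit <- u_fs < false_stop_prob
  la_hit <- u_look < p_look
  pos_any <- first_true_idx(fs_hit | la_hit)
  pos_fs <- first_true_idx(fs_hit)
  is_fs <- !is.na(pos_fs) & !is.na(pos_any) & pos_fs == pos_any
  outcome <- ifelse(is.na(pos_any), "timeout", ifelse(is_fs, "false_stop", "lookaway"))
  tibble(
    lookaway_position = ifelse(outcome == "lookaway", pos_any, NA_integer_),
    outcome = outcome,
    n_events_observed = ifelse(is.na(pos_any), t_max, pos_any)
  )
}

trial_eta <- function(x, params, trial_number) {
  d <- x - params$optimum
  params$baseline_logodds + params$curvature * d^2 + params$linear * d +
    params$trial_slope * trial_number
}

#' Simulate one trial's look-away behavior
#'
#' @param trace A complexity trace from [sequence_complexity()] (needs
#'   `surprisal_bits`).
#' @param params A [hazard_params()] object. `standardize = TRUE` is not
#'   meaningful for a single trial (there is no session to standardize over)
#'   and raises an error.
#' @param trial_number Presentation index of the trial (enters the fatigue
#'   term).
#' @param seed Optional integer seed.
#' @return A one-row tibble: `lookaway_position` (NA unless the infant looked
#'   away), `outcome` (`lookaway`, `false_stop` or `timeout`) and
#'   `n_events_observed`.
#' @export
simulate_trial <- function(trace, params = hazard_params(), trial_number = 1,
                           seed = NULL) {
  stopifnot(inherits(params, "hazard_params"))
  if (params$standardize) {
    abort("`standardize = TRUE` requires a session; use simulate_cohort().")
  }
  x <- trace$surprisal_bits
  if (length(x) < 1L) abort("`trace` must be non-empty.")
  x <- x[seq_len(min(length(x), params$timeout_events))]
  p <- hazard_prob(trial_eta(x, params, trial_number), params$link)
  with_seed_if(seed, simulate_records(matrix(p, nrow = 1L), params$false_stop_prob))
}

#' Simulate a cohort of infants over a session design
#'
#' Computes the session's complexity traces once (they are deterministic
#' given the design), then simulates every infant's pass through the session
#' with an independently shuffled trial order, so the fatigue covariate is
#' decoupled from trial identity just as in the original sessions.
#'
#' @param design A session design from [generate_exp1_session()] or
#'   [generate_exp2_session()].
#' @param n_infants Number of simulated infants (>= 1).
#' @param alpha Observer prior strength used for the traces.
#' @param mode Complexity model driving the hazard: `"marginal"` or
#'   `"transitional"`.
#' @param params A [hazard_params()] object.
#' @param seed Optional integer seed.
#' @return A tibble with one row per (infant, trial): `infant_id`,
#'   `trial_id`, `trial_number` (per-infant presentation order),
#'   `lookaway_position`, `outcome`, `n_events_observed`. The session traces
#'   are attached as attribute `"traces"` (see [cohort_traces()]) along with
#'   the generating `params`, `alpha` and `mode`.
#' @export
simulate_cohort <- function(design, n_infants, alpha = 1,
                            mode = c("marginal", "transitional"),
                            params = hazard_params(), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "hazard_params"))
  n_infants <- check_count(n_infants, "n_infants")
  traces <- session_complexity(design, alpha = alpha, mode = mode)
  n_trials <- nrow(design)
  t_max <- params$timeout_events

  # trials x events complexity matrix (traces are in trial_id order)
  len <- table(traces$trial_id)
  if (length(unique(len)) != 1L) {
    abort("All trials must have equal pre-generated length to simulate a cohort.")
  }
  x_mat <- matrix(traces$surprisal_bits, nrow = n_trials, byrow = TRUE)
  x_mat <- x_mat[, seq_len(min(ncol(x_mat), t_max)), drop = FALSE]
  complexity_center <- complexity_scale <- NULL
  if (params$standardize) {
    complexity_center <- mean(x_mat)
    complexity_scale <- pop_sd(x_mat)
    x_mat <- (x_mat - complexity_center) / complexity_scale
  }

  with_seed_if(seed, {
    trial_of <- as.vector(vapply(seq_len(n_infants), function(i) sample(n_trials),
                                 integer(n_trials)))
    infant_id <- rep(seq_len(n_infants), each = n_trials)
    trial_number <- rep(seq_len(n_trials), times = n_infants)
    d <- x_mat[trial_of, , drop = FALSE] - params$optimum
    eta <- params$baseline_logodds + params$curvature * d^2 + params$linear * d +
      params$trial_slope * trial_number
    p_look <- hazard_prob(eta, params$link)
    rec <- simulate_records(p_look, params$false_stop_prob)
    rec <- dplyr::mutate(rec,
      infant_id = infant_id, trial_id = trial_of, trial_number = trial_number,
      .before = 1L
    )
    attr(rec, "traces") <- traces
    attr(rec, "params") <- params
    attr(rec, "alpha") <- alpha
    attr(rec, "mode") <- mode
    # standardization constants of the generating hazard (stimulus-ensemble
    # scale), kept so recovery fits can target the generating coefficient
    attr(rec, "complexity_center") <- complexity_center
    attr(rec, "complexity_scale") <- complexity_scale
    rec
  })
}

#' Complexity traces attached to a simulated cohort
#'
#' @param records A cohort tibble from [simulate_cohort()].
#' @return The session trace tibble used to drive the hazard; identical to
#'   `session_complexity(design, alpha, mode)` for the generating design.
#' @export
cohort_traces <- function(records) {
  tr <- attr(records, "traces")
  if (is.null(tr)) abort("`records` carries no traces; pass them explicitly.")
  tr
}
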