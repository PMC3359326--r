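#' Apply the standard trial-exclusion rules
#'
#' Discards timeouts (the infant never looked away within the 60 s cap),
#' tracker false stops, and trials in which fewer than `min_events` events
#' were observed before the look-away — too few observations to have formed
#' expectations about the event distribution. A trial with a look-away at
#' exactly the `min_events`-th event is retained.
#'
#' @param records A look-away record tibble (from [simulate_cohort()] or read
#'   from CSV) with columns `outcome` and `n_events_observed`.
#' @param min_events Minimum observed events for retention (default 4).
#' @return The retained records, with an `"exclusion_report"` attribute (see
#'   [exclusion_report()]) giving counts and fractions per category.
#' @export
apply_exclusions <- function(records, min_events = 4L) {
  min_events <- check_count(min_events, "min_events")
  n_total <- nrow(records)
  is_timeout <- records$outcome == "timeout"
  is_false_stop <- records$outcome == "false_stop"
  is_short <- !is_timeout & !is_false_stop & records$n_events_observed < min_events
  keep <- !(is_timeout | is_false_stop | is_short)
  report <- tibble(
    category = c("retained", "timeout", "false_stop", "too_few_events"),
    n = c(sum(keep), sum(is_timeout), sum(is_false_stop), sum(is_short)),
    fraction = if (n_total > 0) c(sum(keep), sum(is_timeout), sum(is_false_stop),
                                  sum(is_short)) / n_total else rep(0, 4)
  )
  out <- records[keep, , drop = FALSE]
  for (a in c("traces", "params", "alpha", "mode",
              "complexity_center", "complexity_scale")) {
    attr(out, a) <- attr(records, a)
  }
  attr(out, "exclusion_report") <- report
  out
}

#' Exclusion report of a filtered record set
#'
#' @param records Output of [apply_exclusions()].
#' @return A tibble with per-category counts and fractions; fractions sum
#'   to 1 over retained + excluded categories.
#' @export
exclusion_report <- function(records) {
  rep <- attr(records, "exclusion_report")
  if (is.null(rep)) abort("`records` has no exclusion report; run apply_exclusions() first.")
  rep
}

#' Sequence-derived covariates for every event of a design
#'
#' For single-box trials: `object_present` (the reveal showed the object) and
#' `same_as_previous` (the reveal matched the previous one; defined as 0 at
#' the first event, which has no predecessor). For three-box trials:
#' `first_appearance` (first time this object has popped up in the trial) and
#' `n_not_yet_appeared` (how many of the three objects have not yet appeared,
#' counting the current event).
#'
#' @param design A session design tibble.
#' @return A tibble keyed by (`trial_id`, `position`) with the covariates for
#'   the design's experiment.
#' @export
design_covariates <- function(design) {
  exp_n <- design$experiment[1]
  purrr::map2_dfr(design$trial_id, design$events, function(id, ev) {
    n <- length(ev)
    base <- tibble(trial_id = id, position = seq_len(n), symbol = ev)
    if (exp_n == 1) {
      base$object_present <- as.integer(ev == "present")
      base$same_as_previous <- as.integer(c(FALSE, ev[-1] == ev[-n]))
    } else {
      first_seen <- !duplicated(ev)
      base$first_appearance <- as.integer(first_seen)
      base$n_not_yet_appeared <- 3L - cumsum(first_seen)
    }
    base
  })
}

#' Expand look-away records into counting-process event rows
#'
#' Builds the analysis table for hazard regression: one row per (infant,
#' trial, at-risk event), from the first event up to and including the event
#' at which the trial ended. `lookaway` is 1 only on the final row of trials
#' that ended in a look-away; trials retained with other outcomes (possible
#' when exclusions are relaxed) contribute fully censored rows. Each row
#' carries the event's complexity and posterior entropy from the trace, the
#' design-derived covariates and the presentation index.
#'
#' @param records Retained look-away records (see [apply_exclusions()]).
#' @param traces Per-trial complexity traces ([session_complexity()]), or a
#'   named list of trace tibbles (e.g. `list(marginal = ..., transitional =
#'   ...)`) to attach several complexity columns with suffixed names.
#' @param design The session design the records were generated from.
#' @return A tibble of event rows with columns `infant_id`, `trial_id`,
#'   `trial_number`, `position`, `lookaway`, `complexity_bits`,
#'   `posterior_entropy` and the design covariates. With a list of traces the
#'   complexity columns are `complexity_bits_<name>` /
#'   `posterior_entropy_<name>`.
#' @export
build_event_table <- function(records, traces = cohort_traces(records), design) {
  if (nrow(records) == 0L) abort("`records` is empty.")
  n_obs <- records$n_events_observed
  idx <- rep(seq_len(nrow(records)), times = n_obs)
  rows <- tibble(
    infant_id = records$infant_id[idx],
    trial_id = records$trial_id[idx],
    trial_number = records$trial_number[idx],
    position = sequence(n_obs),
    lookaway = 0L
  )
  ends <- cumsum(n_obs)
  rows$lookaway[ends] <- as.integer(records$outcome == "lookaway")

  trace_list <- if (inherits(traces, "data.frame")) list(traces) else traces
  nms <- names(trace_list)
  for (i in seq_along(trace_list)) {
    tr <- trace_list[[i]]
    missing_trials <- setdiff(unique(rows$trial_id), unique(tr$trial_id))
    if (length(missing_trials) > 0L) {
      abort(sprintf("No trace for trial(s): %s", paste(missing_trials, collapse = ", ")))
    }
    suffix <- if (length(trace_list) > 1L || !is.null(nms) && nzchar(nms[i] %||% "")) {
      paste0("_", nms[i])
    } else {
      ""
    }
    tr <- dplyr::select(tr, "trial_id", "position", "surprisal_bits", "posterior_entropy")
    names(tr)[3:4] <- paste0(c("complexity_bits", "posterior_entropy"), suffix)
    rows <- dplyr::left_join(rows, tr, by = c("trial_id", "position"))
  }

  dplyr::left_join(rows, design_covariates(design), by = c("trial_id", "position"))
}

#' Standardize complexity and attach its square
#'
#' Shifts and scales each complexity column to mean 0 and (population)
#' standard deviation 1 over all rows of the table, then squares the
#' standardized value — standardize-then-square, which differs from
#' square-then-standardize whenever the complexity distribution is
#' asymmetric.
#'
#' @param rows An event table from [build_event_table()].
#' @param columns Complexity columns to standardize; defaults to every column
#'   starting with `complexity_bits`.
#' @return `rows` with `z_complexity*` and `z_complexity*_sq` columns added
#'   (suffixes follow the complexity column suffixes).
#' @export
standardize_complexity <- function(rows, columns = NULL) {
  if (is.null(columns)) {
    columns <- grep("^complexity_bits", names(rows), value = TRUE)
  }
  if (nrow(rows) < 2L) abort("Standardization needs at least 2 rows.")
  for (col in columns) {
    x <- rows[[col]]
    s <- pop_sd(x)
    if (s == 0) abort(sprintf("`%s` has zero variance; cannot standardize.", col))
    z <- (x - mean(x)) / s
    zname <- sub("^complexity_bits", "z_complexity", col)
    rows[[zname]] <- z
    rows[[paste0(zname, "_sq")]] <- z^2
  }
  rows
}

#' Build the full analysis table in one call
#'
#' Convenience wrapper: [apply_exclusions()], then [build_event_table()],
#' then [standardize_complexity()]. The exclusion report is carried through
#' as an attribute.
#'
#' @inheritParams build_event_table
#' @inheritParams apply_exclusions
#' @return A standardized event table with attribute `"exclusion_report"`.
#' @export
event_table <- function(records, traces = cohort_traces(records), design,
                        min_events = 4L) {
  kept <- apply_exclusions(records, min_events = min_events)
  if (nrow(kept) == 0L) abort("No records survive the exclusion rules.")
  rows <- standardize_complexity(build_event_table(kept, traces, design))
  attr(rows, "exclusion_report") <- exclusion_report(kept)
  rows
}
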