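#' Fit a Cox proportional-hazards model to the event table
#'
#' Fits the partial-likelihood Cox regression on counting-process rows: each
#' at-risk event contributes the interval `(position - 1, position]` with the
#' look-away indicator as the event marker, so covariates may vary event to
#' event within a trial and the baseline hazard over event positions is
#' handled non-parametrically. Ties (many trials ending at the same event
#' index) use the Efron approximation.
#'
#' @param rows An event table from [event_table()] / [build_event_table()].
#' @param covariates Character vector of covariate column names.
#' @return A `lookaway_cox` object; see [tidy()][tidy.lookaway_cox()] and
#'   [glance()][glance.lookaway_cox()].
#' @export
fit_lookaway_cox <- function(rows, covariates) {
  if (length(covariates) < 1L) abort("`covariates` must name at least one column.")
  missing_cols <- setdiff(covariates, names(rows))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Covariate(s) not in `rows`: %s", paste(missing_cols, collapse = ", ")))
  }
  if (sum(rows$lookaway) < 1L) abort("No look-away events in `rows`; nothing to fit.")
  degenerate <- covariates[vapply(covariates, function(v) {
    length(unique(rows[[v]])) < 2L
  }, logical(1))]
  if (length(degenerate) > 0L) {
    abort(sprintf("Constant covariate(s): %s", paste(degenerate, collapse = ", ")))
  }
  fml <- as.formula(paste(
    "survival::Surv(position - 1, position, lookaway) ~",
    paste(covariates, collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = rows, ties = "efron")
  new_lookaway_cox(fit, covariates, rows)
}

new_lookaway_cox <- function(fit, covariates, rows) {
  structure(
    list(
      fit = fit,
      covariates = covariates,
      aic = if (length(covariates) > 0L) AIC(fit) else -2 * fit$loglik[1],
      n_rows = nrow(rows),
      n_events = sum(rows$lookaway)
    ),
    class = "lookaway_cox"
  )
}

#' @export
print.lookaway_cox <- function(x, ...) {
  cat(sprintf(
    "<lookaway_cox> %d at-risk events, %d look-aways, AIC %.1f\n",
    x$n_rows, x$n_events, x$aic
  ))
  if (length(x$covariates) == 0L) {
    cat("  (null model: no covariates)\n")
  } else {
    print(tidy(x))
  }
  invisible(x)
}

null_cox_aic <- function(rows) {
  fit0 <- survival::coxph(
    survival::Surv(position - 1, position, lookaway) ~ 1,
    data = rows, ties = "efron"
  )
  -2 * fit0$loglik[1]
}

#' Forward stepwise covariate selection by AIC
#'
#' Starting from the empty (baseline-hazard-only) model, repeatedly adds the
#' candidate covariate that most lowers the Akaike information criterion,
#' stopping when no addition lowers it. Covariates are only ever added, never
#' removed, so — as with any AIC-based step — non-significant covariates can
#' end up retained when they buy more than 2 log-likelihood points.
#'
#' @inheritParams fit_lookaway_cox
#' @param candidates Character vector of candidate covariates; see
#'   [default_candidates()].
#' @return A `lookaway_cox` for the selected model, with the addition order
#'   and AIC trace in `$steps` (a tibble: step, added covariate, AIC).
#' @export
stepwise_aic_cox <- function(rows, candidates = default_candidates(1)) {
  if (length(candidates) < 1L) abort("`candidates` must be non-empty.")
  constant <- candidates[vapply(candidates, function(v) {
    length(unique(rows[[v]])) < 2L
  }, logical(1))]
  if (length(constant) > 0L) {
    warn(sprintf("Dropping constant candidate(s): %s", paste(constant, collapse = ", ")))
    candidates <- setdiff(candidates, constant)
  }
  selected <- character(0)
  current_aic <- null_cox_aic(rows)
  steps <- tibble(step = 0L, added = NA_character_, aic = current_aic)
  remaining <- candidates
  repeat {
    if (length(remaining) == 0L) break
    trial_aic <- vapply(remaining, function(v) {
      fit_lookaway_cox(rows, c(selected, v))$aic
    }, numeric(1))
    best <- which.min(trial_aic)
    if (trial_aic[best] >= current_aic) break
    selected <- c(selected, remaining[best])
    current_aic <- trial_aic[best]
    steps <- dplyr::bind_rows(steps, tibble(
      step = length(selected), added = remaining[best], aic = current_aic
    ))
    remaining <- remaining[-best]
  }
  out <- if (length(selected) > 0L) {
    fit_lookaway_cox(rows, selected)
  } else {
    structure(
      list(fit = NULL, covariates = character(0), aic = current_aic,
           n_rows = nrow(rows), n_events = sum(rows$lookaway)),
      class = "lookaway_cox"
    )
  }
  out$steps <- steps
  out
}

#' Default Cox covariate candidates per experiment
#'
#' Single-box sessions consider linear and squared standardized complexity,
#' whether the object was present, whether the reveal matched the previous
#' one, the presentation index (fatigue) and the posterior's differential
#' entropy (model uncertainty). Three-box sessions drop `object_present`
#' (an object always appears) and add `first_appearance` and
#' `n_not_yet_appeared`.
#'
#' @param experiment 1 or 2.
#' @return Character vector of covariate names.
#' @export
default_candidates <- function(experiment) {
  if (experiment == 1) {
    c("z_complexity", "z_complexity_sq", "object_present", "same_as_previous",
      "trial_number", "posterior_entropy")
  } else {
    c("z_complexity", "z_complexity_sq", "trial_number", "posterior_entropy",
      "first_appearance", "n_not_yet_appeared")
  }
}

#' Joint comparison of transitional vs. marginal complexity
#'
#' Enters the squared standardized complexity of both observer variants into
#' one Cox regression (plus any additional covariates), to ask which variant
#' carries the look-away signal when both compete. Also reports the Pearson
#' correlation between the two raw complexity columns, since the two
#' measures are closely related on realistic designs and near-collinearity
#' is the expected regime.
#'
#' @param rows An event table carrying both complexity variants, e.g. from
#'   `build_event_table(records, list(marginal = ..., transitional = ...),
#'   design)` followed by [standardize_complexity()].
#' @param extra_covariates Additional covariates entered alongside the two
#'   squared-complexity terms (default `trial_number`).
#' @return A list with `fit` (the joint `lookaway_cox`) and `correlation`
#'   (Pearson correlation of the marginal and transitional complexity
#'   columns across rows).
#' @export
compare_complexity_models <- function(rows, extra_covariates = "trial_number") {
  needed <- c("z_complexity_marginal_sq", "z_complexity_transitional_sq")
  if (!all(needed %in% names(rows))) {
    abort("`rows` must carry marginal and transitional standardized complexity (see build_event_table with a trace list).")
  }
  r <- cor(rows$complexity_bits_marginal, rows$complexity_bits_transitional)
  if (cor(rows$z_complexity_marginal_sq, rows$z_complexity_transitional_sq) > 1 - 1e-10) {
    abort("Marginal and transitional complexity are numerically collinear; the joint fit is not identified.")
  }
  fit <- fit_lookaway_cox(rows, c(needed, extra_covariates))
  list(fit = fit, correlation = r)
}

#' @describeIn fit_lookaway_cox Tidy coefficient table: one row per
#'   covariate with `estimate` (log-hazard coefficient), `exp_estimate`
#'   (hazard ratio), `std.error`, `statistic` (z) and `p.value`.
#' @param x A `lookaway_cox` object.
#' @param ... Unused.
#' @method tidy lookaway_cox
#' @export
tidy.lookaway_cox <- function(x, ...) {
  if (length(x$covariates) == 0L) {
    return(tibble(
      term = character(0), estimate = numeric(0), exp_estimate = numeric(0),
      std.error = numeric(0), statistic = numeric(0), p.value = numeric(0)
    ))
  }
  est <- coef(x$fit)
  se <- sqrt(diag(vcov(x$fit)))
  z <- est / se
  tibble(
    term = names(est),
    estimate = unname(est),
    exp_estimate = exp(unname(est)),
    std.error = unname(se),
    statistic = unname(z),
    p.value = 2 * pnorm(-abs(unname(z)))
  )
}

#' @describeIn fit_lookaway_cox One-row model summary: AIC, number of
#'   at-risk rows, number of look-away events and selected covariate count.
#' @method glance lookaway_cox
#' @export
glance.lookaway_cox <- function(x, ...) {
  tibble(
    aic = x$aic,
    n_rows = x$n_rows,
    n_events = x$n_events,
    n_covariates = length(x$covariates)
  )
}
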