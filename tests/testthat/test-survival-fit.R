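# Small synthetic event tables built directly (no full pipeline) keep the
# regression checks fast: trials with geometric look-aways and iid covariates.
synthetic_rows <- function(n_trials = 150, t_max = 20, h = 0.15,
                           beta = 0, covariate = NULL,
                           link = c("logistic", "cloglog")) {
  link <- match.arg(link)
  rows <- purrr::map_dfr(seq_len(n_trials), function(i) {
    x <- if (is.null(covariate)) rnorm(t_max) else covariate(t_max)
    p <- if (link == "logistic") {
      plogis(qlogis(h) + beta * x)
    } else {
      # grouped proportional hazards: beta lives on the Cox log-hazard scale
      -expm1(-exp(log(-log(1 - h)) + beta * x))
    }
    hit <- which(runif(t_max) < p)
    stop_at <- if (length(hit) > 0) hit[1] else t_max
    tibble::tibble(
      infant_id = 1L, trial_id = i, trial_number = i,
      position = seq_len(stop_at),
      lookaway = c(rep(0L, stop_at - 1L), as.integer(length(hit) > 0)),
      x = x[seq_len(stop_at)]
    )
  })
  rows
}

test_that("coefficient table satisfies the exp(coef) identity and is order-invariant", {
  withr::with_seed(101, rows <- synthetic_rows(beta = 0.5))
  fit <- fit_lookaway_cox(rows, "x")
  td <- tidy(fit)
  expect_equal(td$exp_estimate, exp(td$estimate), tolerance = 1e-9)
  expect_equal(td$p.value, 2 * pnorm(-abs(td$statistic)))

  shuffled <- withr::with_seed(5, rows[sample(nrow(rows)), ])
  expect_equal(tidy(fit_lookaway_cox(shuffled, "x"))$estimate, td$estimate)

  g <- glance(fit)
  expect_identical(g$n_rows, nrow(rows))
  expect_identical(g$n_events, sum(rows$lookaway))
})

test_that("degenerate designs are rejected with informative errors", {
  withr::with_seed(102, rows <- synthetic_rows(n_trials = 30))
  rows$const <- 1
  expect_error(fit_lookaway_cox(rows, "const"), "Constant covariate")
  expect_error(fit_lookaway_cox(rows, "nope"), "not in")
  no_events <- dplyr::mutate(rows, lookaway = 0L)
  expect_error(fit_lookaway_cox(no_events, "x"), "No look-away")
  expect_error(fit_lookaway_cox(rows, character(0)), "at least one")
})

test_that("a pure-noise covariate is significant at roughly the nominal rate", {
  withr::with_seed(103, {
    zs <- purrr::map_dbl(1:300, function(i) {
      rows <- synthetic_rows(n_trials = 60, beta = 0)
      tidy(fit_lookaway_cox(rows, "x"))$statistic
    })
  })
  # |z| < 2 has nominal probability 0.954; allow 2.5 binomial SE below it
  expect_gte(mean(abs(zs) < 2), 0.93)
})

test_that("a known log-hazard effect is recovered without systematic bias", {
  withr::with_seed(104, {
    ests <- purrr::map_dfr(1:40, function(i) {
      rows <- synthetic_rows(n_trials = 120, h = 0.08, beta = 0.356,
                             covariate = function(n) rnorm(n)^2 - 1,
                             link = "cloglog")
      td <- tidy(fit_lookaway_cox(rows, "x"))
      tibble::tibble(est = td$estimate, se = td$std.error)
    })
  })
  expect_gte(mean(abs(ests$est - 0.356) < 2 * ests$se), 0.9)
  expect_lt(abs(mean(ests$est) - 0.356), 0.05)
})

test_that("forward AIC selection keeps signal and drops noise", {
  withr::with_seed(105, {
    picks <- purrr::map(1:25, function(i) {
      rows <- synthetic_rows(n_trials = 120, beta = 0.6)
      rows$noise1 <- rnorm(nrow(rows))
      rows$noise2 <- rnorm(nrow(rows))
      stepwise_aic_cox(rows, c("x", "noise1", "noise2"))$covariates
    })
  })
  expect_gte(mean(purrr::map_lgl(picks, ~ "x" %in% .x)), 0.9)

  withr::with_seed(106, {
    null_picks <- purrr::map_int(1:25, function(i) {
      rows <- synthetic_rows(n_trials = 80, beta = 0)
      rows$noise1 <- rnorm(nrow(rows))
      length(stepwise_aic_cox(rows, c("x", "noise1"))$covariates)
    })
  })
  # the empty model is the modal outcome under pure noise (AIC penalty 2)
  expect_gt(mean(null_picks == 0), 0.5)

  # AIC trace starts at the null model and strictly decreases
  withr::with_seed(107, rows <- synthetic_rows(n_trials = 120, beta = 0.6))
  fit <- stepwise_aic_cox(rows, c("x"))
  expect_identical(fit$steps$step[1], 0L)
  expect_true(all(diff(fit$steps$aic) < 0))
})

test_that("stepwise retains both fatigue and quadratic effects when generated", {
  design <- generate_exp2_session(seed = 111)
  params <- hazard_params(standardize = TRUE, optimum = 0, curvature = 0.5,
                          linear = 0, trial_slope = 0.05, link = "cloglog",
                          baseline_logodds = -2.6)
  records <- simulate_cohort(design, n_infants = 40, params = params, seed = 112)
  rows <- event_table(records, design = design)
  fit <- stepwise_aic_cox(rows, c("z_complexity_sq", "trial_number"))
  expect_setequal(fit$covariates, c("z_complexity_sq", "trial_number"))
})

test_that("joint transitional/marginal comparison reports correlation and rejects collinearity", {
  cohort <- small_cohort(n_infants = 15, mode = "transitional", seed = 121)
  traces <- list(
    marginal = session_complexity(cohort$design, mode = "marginal"),
    transitional = cohort_traces(cohort$records)
  )
  kept <- apply_exclusions(cohort$records)
  rows <- standardize_complexity(build_event_table(kept, traces, cohort$design))
  cmp <- compare_complexity_models(rows)
  expect_s3_class(cmp$fit, "lookaway_cox")
  expect_gt(cmp$correlation, 0.7)
  expect_setequal(
    tidy(cmp$fit)$term,
    c("z_complexity_marginal_sq", "z_complexity_transitional_sq", "trial_number")
  )

  dup <- rows
  dup$z_complexity_transitional_sq <- dup$z_complexity_marginal_sq
  dup$complexity_bits_transitional <- dup$complexity_bits_marginal
  expect_error(compare_complexity_models(dup), "collinear")
  expect_error(compare_complexity_models(rows[, 1:5]), "marginal and transitional")
})
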