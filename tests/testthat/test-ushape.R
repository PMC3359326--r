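test_that("binned probabilities aggregate raw look-away rates", {
  rows <- tibble::tibble(
    complexity_bits = c(0.1, 0.4, 1.1, 1.4, 2.1, 2.6),
    position = 1:6,
    lookaway = c(0L, 1L, 0L, 0L, 0L, 1L)
  )
  b1 <- bin_lookaway(rows, n_bins = 1)
  expect_equal(b1$prob, 2 / 6)
  expect_identical(b1$n_events, 6L)

  b3 <- bin_lookaway(rows, n_bins = 3)
  expect_equal(sum(b3$n_events), 6L)
  expect_equal(b3$prob, c(0.5, 0, 0.5))
  expect_equal(b3$se[2], 0)

  # all-censored rows give zero probabilities
  b0 <- bin_lookaway(dplyr::mutate(rows, lookaway = 0L), n_bins = 2)
  expect_true(all(b0$prob == 0))

  # empty bins are reported, not dropped
  gap <- tibble::tibble(complexity_bits = c(rep(0.1, 5), rep(3, 5)),
                        position = 1, lookaway = 0L)
  bg <- bin_lookaway(gap, n_bins = 4)
  expect_identical(nrow(bg), 4L)
  expect_true(any(bg$n_events == 0))
  expect_true(any(is.na(bg$prob)))

  # equal-count bins balance event counts
  cohort <- small_cohort(n_infants = 10, seed = 131)
  big <- event_table(cohort$records, design = cohort$design)
  bq <- bin_lookaway(big, n_bins = 5, method = "count")
  expect_lt(max(bq$n_events) / max(1, min(bq$n_events)), 4)
})

test_that("the smooth fit recovers an interior minimum near the generating optimum", {
  cohort <- small_cohort(n_infants = 30, seed = 141)
  rows <- event_table(cohort$records, design = cohort$design)
  us <- fit_ushape(rows)
  expect_true(us$interior)
  expect_lt(abs(us$minimum_bits - 1.25), 0.35)
  expect_true(all(us$curve$fitted_prob > 0 & us$curve$fitted_prob < 1))
  expect_true(all(us$curve$upper >= us$curve$fitted_prob))
  td <- tidy(us)
  expect_identical(nrow(td), 200L)
  expect_identical(glance(us)$minimum_bits, us$minimum_bits)
})

test_that("a flat generator yields an essentially linear-or-flat partial effect", {
  cohort <- small_cohort(n_infants = 40, seed = 151, params = flat_params(0.12))
  rows <- event_table(cohort$records, design = cohort$design, min_events = 1)
  us <- fit_ushape(rows)
  # the complexity smooth should be indistinguishable from no effect
  s_tab <- summary(us$gam)$s.table
  p_cmp <- s_tab[grep("complexity", rownames(s_tab)), "p-value"]
  expect_gt(p_cmp, 0.01)
  expect_lt(us$edf_complexity, 4)
})

test_that("monotone generators are flagged as boundary minima", {
  # linear-only hazard, steeply increasing in complexity: no interior U
  params <- hazard_params(baseline_logodds = -3, curvature = 0, optimum = 0,
                          linear = 1.2, trial_slope = 0, false_stop_prob = 0)
  cohort <- small_cohort(n_infants = 40, seed = 161, params = params)
  rows <- event_table(cohort$records, design = cohort$design, min_events = 1)
  us <- fit_ushape(rows)
  expect_false(us$interior && abs(us$minimum_bits - min(rows$complexity_bits)) > 0.3)
})

test_that("the minimum is invariant to affine rescaling of position", {
  cohort <- small_cohort(n_infants = 25, seed = 171)
  rows <- event_table(cohort$records, design = cohort$design)
  us1 <- fit_ushape(rows)
  rows2 <- dplyr::mutate(rows, position = 2 * position + 5)
  us2 <- fit_ushape(rows2)
  expect_lt(abs(us1$minimum_bits - us2$minimum_bits), 0.05)
})

test_that("binned rates agree with the smooth fit within binomial error", {
  cohort <- small_cohort(n_infants = 30, seed = 181)
  all_rows <- event_table(cohort$records, design = cohort$design)
  us <- fit_ushape(all_rows)
  # compare on the at-risk rows the smooth was fit to
  rows <- all_rows[all_rows$position >= us$min_position, ]
  bins <- bin_lookaway(rows, n_bins = 5)
  fitted <- predict(
    us$gam,
    newdata = data.frame(complexity = rows$complexity_bits, position = rows$position),
    type = "response"
  )
  idx <- findInterval(rows$complexity_bits,
                      c(bins$lower[1], bins$upper), rightmost.closed = TRUE,
                      all.inside = TRUE)
  mean_fit <- tapply(fitted, idx, mean)
  for (b in seq_len(nrow(bins))) {
    if (bins$n_events[b] >= 30) {
      se <- sqrt(max(bins$prob[b] * (1 - bins$prob[b]), 1e-6) / bins$n_events[b])
      expect_lt(abs(bins$prob[b] - mean_fit[[as.character(b)]]), 2.5 * se + 0.01)
    }
  }
  expect_error(fit_ushape(rows[1:10, ]), "50 rows")
})
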