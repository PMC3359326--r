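#' Raw look-away probability binned by complexity
#'
#' Pools all at-risk events, partitions the observed complexity range into
#' bins, and reports each bin's raw look-away probability with a binomial
#' standard error — the "diamonds" usually plotted over the smooth fit.
#'
#' @param rows An event table with `complexity_bits` and `lookaway` columns.
#' @param n_bins Number of bins (default 5).
#' @param method `"width"` for equal-width bins over the observed range,
#'   `"count"` for equal-count (quantile) bins.
#' @param complexity_col Name of the complexity column to bin on.
#' @return A tibble with one row per bin: `bin`, `lower`, `upper`,
#'   `midpoint`, `n_events`, `n_lookaways`, `prob`, `se`. Empty bins are
#'   kept, with `n_events = 0` and `NA` probability.
#' @export
bin_lookaway <- function(rows, n_bins = 5L, method = c("width", "count"),
                         complexity_col = "complexity_bits") {
  method <- match.arg(method)
  n_bins <- check_count(n_bins, "n_bins")
  if (nrow(rows) == 0L) abort("`rows` is empty.")
  x <- rows[[complexity_col]]
  if (n_bins == 1L) {
    breaks <- range(x)
  } else if (method == "width") {
    breaks <- seq(min(x), max(x), length.out = n_bins + 1L)
  } else {
    breaks <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1L)))
    if (length(breaks) < 2L) abort("Too few distinct complexity values for quantile bins.")
    n_bins <- length(breaks) - 1L
  }
  bin <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  out <- tibble(
    bin = seq_len(n_bins),
    lower = breaks[-length(breaks)],
    upper = breaks[-1]
  )
  tally <- dplyr::summarise(
    dplyr::group_by(tibble(bin = bin, lookaway = rows$lookaway), .data$bin),
    n_events = dplyr::n(), n_lookaways = sum(.data$lookaway), .groups = "drop"
  )
  out <- dplyr::left_join(out, tally, by = "bin")
  out$n_events[is.na(out$n_events)] <- 0L
  out$n_lookaways[is.na(out$n_lookaways)] <- 0L
  dplyr::mutate(out,
    midpoint = (.data$lower + .data$upper) / 2,
    prob = ifelse(.data$n_events > 0, .data$n_lookaways / .data$n_events, NA_real_),
    se = ifelse(.data$n_events > 0,
                sqrt(.data$prob * (1 - .data$prob) / .data$n_events), NA_real_)
  )
}

#' Smooth binomial fit of look-away probability on complexity
#'
#' Fits a generalized additive model with binomial link — look-away
#' indicator on a smooth of complexity plus a smooth of sequence position —
#' and extracts the complexity at which the partial effect of complexity is
#' minimized. Smoothing parameters are selected by generalized
#' cross-validation. A minimum at the edge of the observed complexity range
#' is flagged (`interior = FALSE`), since a U-shape claim requires an
#' interior minimum.
#'
#' Because trials observed for fewer than four events are excluded before
#' analysis, no look-away can be observed before the fourth event: rows at
#' earlier positions have structurally zero conditional hazard and would
#' distort the complexity smooth. By default the fit therefore starts at the
#' earliest position at which a look-away is observed at all; set
#' `min_position = 1` to force the full table in.
#'
#' @param rows An event table (>= 50 rows) with `complexity_bits`,
#'   `position` and `lookaway`.
#' @param k_complexity,k_position Basis dimensions for the two smooths.
#' @param grid_size Number of grid points at which the curve is evaluated.
#' @param complexity_col Name of the complexity column.
#' @param min_position Smallest event position entering the fit; `NULL`
#'   (default) uses the earliest position with an observed look-away.
#' @return A `lookaway_ushape` object: `curve` (grid tibble with the fitted
#'   look-away probability at the median position, its standard-error band
#'   and the complexity partial effect), `minimum_bits`, `interior`,
#'   `edf_complexity` and the underlying `gam` fit.
#' @export
fit_ushape <- function(rows, k_complexity = 10, k_position = 5,
                       grid_size = 200L, complexity_col = "complexity_bits",
                       min_position = NULL) {
  if (is.null(min_position)) {
    ev_pos <- rows$position[rows$lookaway == 1]
    min_position <- if (length(ev_pos) > 0L) min(ev_pos) else 1L
  }
  rows <- rows[rows$position >= min_position, , drop = FALSE]
  if (nrow(rows) < 50L) abort("Need at least 50 rows for a smooth fit.")
  dat <- tibble(
    lookaway = rows$lookaway,
    complexity = rows[[complexity_col]],
    position = rows$position
  )
  k_c <- min(k_complexity, length(unique(dat$complexity)) - 1L)
  k_p <- min(k_position, length(unique(dat$position)) - 1L)
  if (k_c < 3L) abort("Too few distinct complexity values for a smooth.")
  fml <- if (k_p >= 3L) {
    lookaway ~ s(complexity, k = k_c) + s(position, k = k_p)
  } else {
    lookaway ~ s(complexity, k = k_c)
  }
  fit <- mgcv::gam(fml, family = stats::binomial(), data = dat, method = "GCV.Cp")

  rng <- range(dat$complexity)
  grid <- tibble(
    complexity = seq(rng[1], rng[2], length.out = grid_size),
    position = median(dat$position)
  )
  pr <- predict(fit, newdata = grid, type = "link", se.fit = TRUE)
  terms <- predict(fit, newdata = grid, type = "terms")
  partial <- terms[, grep("complexity", colnames(terms), fixed = TRUE)[1]]
  curve <- dplyr::mutate(grid,
    fitted_prob = plogis(as.numeric(pr$fit)),
    lower = plogis(as.numeric(pr$fit - 2 * pr$se.fit)),
    upper = plogis(as.numeric(pr$fit + 2 * pr$se.fit)),
    partial_effect = as.numeric(partial)
  )
  i_min <- which.min(curve$partial_effect)
  interior <- i_min > 1L && i_min < nrow(curve)
  edf_c <- sum(fit$edf[grep("complexity", names(coef(fit)), fixed = TRUE)])
  structure(
    list(
      curve = curve,
      minimum_bits = curve$complexity[i_min],
      interior = interior,
      edf_complexity = edf_c,
      min_position = min_position,
      n_rows = nrow(dat),
      n_lookaways = sum(dat$lookaway),
      gam = fit
    ),
    class = "lookaway_ushape"
  )
}

#' @export
print.lookaway_ushape <- function(x, ...) {
  cat(sprintf(
    "<lookaway_ushape> %d events, %d look-aways\n", x$n_rows, x$n_lookaways
  ))
  cat(sprintf(
    "  complexity partial-effect minimum at %.3f bits (%s), edf %.2f\n",
    x$minimum_bits, if (x$interior) "interior" else "boundary", x$edf_complexity
  ))
  invisible(x)
}

#' @describeIn fit_ushape The fitted curve as a tibble (complexity grid,
#'   fitted probability, SE band, partial effect).
#' @param x A `lookaway_ushape` object.
#' @param ... Unused.
#' @method tidy lookaway_ushape
#' @export
tidy.lookaway_ushape <- function(x, ...) {
  x$curve
}

#' @describeIn fit_ushape One-row summary: minimum location, interior flag,
#'   effective degrees of freedom of the complexity smooth, data size.
#' @method glance lookaway_ushape
#' @export
glance.lookaway_ushape <- function(x, ...) {
  tibble(
    minimum_bits = x$minimum_bits,
    interior = x$interior,
    edf_complexity = x$edf_complexity,
    n_rows = x$n_rows,
    n_lookaways = x$n_lookaways
  )
}
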