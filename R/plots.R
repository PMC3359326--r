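#' Plot a U-shape summary
#'
#' Reproduces the standard layout for this analysis: the smooth fitted
#' look-away probability over complexity with its standard-error band, raw
#' binned probabilities as diamonds, and a rug of observed complexity
#' values.
#'
#' @param object A `lookaway_ushape` from [fit_ushape()].
#' @param bins Optional [bin_lookaway()] tibble to overlay; pass `NULL` to
#'   omit the diamonds.
#' @param rug_data Optional event table whose `complexity_bits` values are
#'   drawn as a rug.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lookaway_ushape
#' @export
autoplot.lookaway_ushape <- function(object, bins = NULL, rug_data = NULL, ...) {
  p <- ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$complexity)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      fill = "grey80", alpha = 0.6
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted_prob), linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = object$minimum_bits, linetype = "dotted") +
    ggplot2::labs(
      x = "Complexity (bits)",
      y = "Look-away probability",
      title = sprintf(
        "Smooth look-away hazard (minimum at %.2f bits%s)",
        object$minimum_bits, if (object$interior) "" else ", boundary"
      )
    ) +
    ggplot2::theme_minimal()
  if (!is.null(bins)) {
    ok <- bins[!is.na(bins$prob), , drop = FALSE]
    p <- p + ggplot2::geom_point(
      data = ok, ggplot2::aes(x = .data$midpoint, y = .data$prob),
      shape = 18, colour = "red3", size = 3
    ) + ggplot2::geom_errorbar(
      data = ok,
      ggplot2::aes(x = .data$midpoint, ymin = .data$prob - .data$se,
                   ymax = .data$prob + .data$se),
      colour = "red3", width = 0
    )
  }
  if (!is.null(rug_data)) {
    p <- p + ggplot2::geom_rug(
      data = rug_data, ggplot2::aes(x = .data$complexity_bits),
      sides = "b", alpha = 0.1, inherit.aes = FALSE
    )
  }
  p
}

#' Coefficient (forest) plot for a Cox fit
#'
#' @param object A `lookaway_cox` from [fit_lookaway_cox()] or
#'   [stepwise_aic_cox()].
#' @param ... Unused.
#' @return A ggplot object showing each coefficient with a 95% interval.
#' @method autoplot lookaway_cox
#' @export
autoplot.lookaway_cox <- function(object, ...) {
  td <- tidy(object)
  if (nrow(td) == 0L) abort("Null model: nothing to plot.")
  td$lower <- td$estimate - 1.96 * td$std.error
  td$upper <- td$estimate + 1.96 * td$std.error
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lower, xmax = .data$upper), height = 0.15
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Log hazard ratio", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a complexity trace
#'
#' Per-event surprisal for one or more trials, as step-to-step trajectories.
#'
#' @param traces A trace tibble from [sequence_complexity()] (optionally with
#'   a `trial_id` column, as from [session_complexity()]).
#' @return A ggplot object.
#' @export
plot_complexity_trace <- function(traces) {
  if (!"trial_id" %in% names(traces)) traces$trial_id <- 1L
  ggplot2::ggplot(traces, ggplot2::aes(
    x = .data$position, y = .data$surprisal_bits, group = .data$trial_id
  )) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Event position", y = "Surprisal (bits)") +
    ggplot2::theme_minimal()
}
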