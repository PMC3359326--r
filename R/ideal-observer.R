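#' Create a Dirichlet-multinomial observer state
#'
#' The observer maintains event counts over a finite alphabet together with a
#' symmetric Dirichlet prior of strength `alpha`. The latent multinomial
#' parameters are always integrated out, so the state is just
#' counts-plus-prior and all predictive queries have closed forms.
#'
#' @param alphabet Character vector of unique symbol names (length >= 2).
#' @param alpha Prior strength (pseudo-count) added to every symbol; must be
#'   positive. `alpha = 1` is a uniform prior over event distributions.
#' @param counts Optional named numeric vector of non-negative observation
#'   counts, one per symbol. Defaults to all zero.
#' @return An object of class `mdm_state`.
#' @examples
#' s <- mdm_state(c("present", "absent"))
#' posterior_predictive(s)
#' @export
mdm_state <- function(alphabet, alpha = 1, counts = NULL) {
  alphabet <- as.character(alphabet)
  if (length(alphabet) < 2L || anyDuplicated(alphabet) > 0L) {
    abort("`alphabet` must contain at least 2 unique symbols.")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0) {
    abort("`alpha` must be a single positive number.")
  }
  if (is.null(counts)) {
    counts <- setNames(rep(0, length(alphabet)), alphabet)
  } else {
    if (is.null(names(counts))) names(counts) <- alphabet
    if (!setequal(names(counts), alphabet) || any(counts < 0)) {
      abort("`counts` must be non-negative and named by the alphabet.")
    }
    counts <- counts[alphabet]
  }
  structure(
    list(alphabet = alphabet, alpha = alpha, counts = counts),
    class = "mdm_state"
  )
}

#' @export
print.mdm_state <- function(x, ...) {
  cat(sprintf(
    "<mdm_state> K = %d, alpha = %g, N = %g\n",
    length(x$alphabet), x$alpha, sum(x$counts)
  ))
  print(x$counts)
  invisible(x)
}

check_symbol <- function(state, event) {
  if (length(event) != 1L || !(event %in% state$alphabet)) {
    abort(sprintf("Symbol '%s' is not in the observer's alphabet.", paste(event, collapse = ",")))
  }
  invisible(event)
}

#' Posterior-predictive distribution over the next event
#'
#' Integrating the multinomial likelihood against the Dirichlet posterior
#' gives the predictive probability `(n_i + alpha) / (N + K * alpha)` for each
#' symbol `i`, where `N` is the total observation count and `K` the alphabet
#' size. With no observations and `alpha = 1` this is uniform: 50-50 for a
#' binary alphabet, 33-33-33 for a three-symbol alphabet.
#'
#' @param state An [mdm_state()].
#' @return Named numeric vector of predictive probabilities summing to 1.
#' @export
posterior_predictive <- function(state) {
  stopifnot(inherits(state, "mdm_state"))
  a <- state$counts + state$alpha
  a / sum(a)
}

#' Surprisal (information content) of an event
#'
#' The negative log posterior-predictive probability of `event` under the
#' current state: the number of bits (for `log_base = 2`) conveyed by
#' observing it. Because `alpha > 0`, every symbol has nonzero predictive
#' probability and surprisal is always finite.
#'
#' @inheritParams posterior_predictive
#' @param event A single symbol from the state's alphabet.
#' @param log_base Base of the logarithm; 2 gives bits, `exp(1)` gives nats.
#' @return Non-negative surprisal.
#' @export
surprisal <- function(state, event, log_base = 2) {
  check_symbol(state, event)
  p <- posterior_predictive(state)[[event]]
  -log(p, base = log_base)
}

#' Update the observer with one observed event
#'
#' @inheritParams surprisal
#' @return A new `mdm_state` with the event's count incremented by 1.
#' @export
mdm_update <- function(state, event) {
  check_symbol(state, event)
  state$counts[[event]] <- state$counts[[event]] + 1
  state
}

#' Differential entropy of the posterior over event distributions
#'
#' Entropy of the Dirichlet density with parameters `a = counts + alpha`:
#' `ln B(a) + (a0 - K) psi(a0) - sum((a_j - 1) psi(a_j))` where
#' `a0 = sum(a)` and `psi` is the digamma function. Reported in nats; as a
#' differential entropy it may be negative, and it decreases as the observer
#' becomes more certain about the event distribution.
#'
#' @inheritParams posterior_predictive
#' @return Differential entropy in nats.
#' @export
posterior_entropy <- function(state) {
  stopifnot(inherits(state, "mdm_state"))
  a <- state$counts + state$alpha
  dirichlet_entropy(a)
}

dirichlet_entropy <- function(a) {
  a0 <- sum(a)
  k <- length(a)
  log_beta <- sum(lgamma(a)) - lgamma(a0)
  log_beta + (a0 - k) * digamma(a0) - sum((a - 1) * digamma(a))
}

#' Score a whole event sequence with the ideal observer
#'
#' Walks through `events`, scoring each event with the state built from the
#' events before it (predict-then-update), and returns the per-event
#' complexity trace. In `"marginal"` mode successive events are treated as
#' exchangeable draws from one distribution; in `"transitional"` mode the
#' predictive distribution is conditioned on the immediately preceding event
#' (first-order Markov), with one count row per conditioning symbol sharing a
#' single symmetric `alpha`. The first event of a transitional trace has no
#' predecessor and is scored with the marginal (prior-only) model, so traces
#' are always full length.
#'
#' @param events Character vector of observed symbols (length >= 1).
#' @param alphabet Symbol alphabet; defaults to the sorted unique values of
#'   `events`, but passing it explicitly is safer when some symbols may not
#'   occur.
#' @param alpha Prior strength, shared across conditioning rows.
#' @param mode `"marginal"` or `"transitional"`.
#' @param log_base Base for the surprisal logarithm (2 = bits).
#' @param .collapse_transitions Internal: make the transitional model share a
#'   single count row across conditioning symbols, which reduces it exactly
#'   to the marginal model (used for equivalence checks).
#' @return A tibble with one row per event: `position`, `symbol`,
#'   `predictive_prob`, `surprisal_bits`, `posterior_entropy` (nats, of the
#'   state used for prediction) and `mode`.
#' @examples
#' sequence_complexity(c("1", "1", "0"), alphabet = c("0", "1"))
#' @export
sequence_complexity <- function(events, alphabet = NULL, alpha = 1,
                                mode = c("marginal", "transitional"),
                                log_base = 2,
                                .collapse_transitions = FALSE) {
  mode <- match.arg(mode)
  events <- as.character(events)
  if (length(events) < 1L) abort("`events` must contain at least one event.")
  if (is.null(alphabet)) alphabet <- sort(unique(events))
  if (!all(events %in% alphabet)) abort("All events must belong to `alphabet`.")
  k <- length(alphabet)
  n <- length(events)

  prob <- numeric(n)
  entropy <- numeric(n)

  if (mode == "marginal") {
    counts <- setNames(rep(0, k), alphabet)
    for (t in seq_len(n)) {
      a <- counts + alpha
      prob[t] <- a[[events[t]]] / sum(a)
      entropy[t] <- dirichlet_entropy(a)
      counts[[events[t]]] <- counts[[events[t]]] + 1
    }
  } else {
    trans <- matrix(0, nrow = k, ncol = k, dimnames = list(alphabet, alphabet))
    # conditioning-blind variant: one shared row counting every observed
    # event, which reduces the transitional model exactly to the marginal
    shared <- setNames(rep(0, k), alphabet)
    prior_a <- rep(alpha, k)
    # event 1: no predecessor; score with the prior-only marginal model
    prob[1] <- 1 / k
    entropy[1] <- dirichlet_entropy(prior_a)
    shared[[events[1L]]] <- shared[[events[1L]]] + 1
    if (n > 1L) {
      for (t in 2:n) {
        row <- if (.collapse_transitions) shared else trans[events[t - 1L], ]
        a <- row + alpha
        prob[t] <- a[[events[t]]] / sum(a)
        entropy[t] <- dirichlet_entropy(a)
        trans[events[t - 1L], events[t]] <- trans[events[t - 1L], events[t]] + 1
        shared[[events[t]]] <- shared[[events[t]]] + 1
      }
    }
  }

  tibble(
    position = seq_len(n),
    symbol = events,
    predictive_prob = prob,
    surprisal_bits = -log(prob, base = log_base),
    posterior_entropy = entropy,
    mode = mode
  )
}

#' Complexity traces for every trial of a session design
#'
#' @param design A session design tibble from [generate_exp1_session()] or
#'   [generate_exp2_session()] (needs `trial_id`, `experiment` and an
#'   `events` list-column).
#' @inheritParams sequence_complexity
#' @return A tibble of per-event traces for all trials, keyed by `trial_id`.
#' @export
session_complexity <- function(design, alpha = 1,
                               mode = c("marginal", "transitional"),
                               log_base = 2) {
  mode <- match.arg(mode)
  alphabet <- design_alphabet(design)
  purrr::map2_dfr(design$trial_id, design$events, function(id, ev) {
    tr <- sequence_complexity(ev, alphabet = alphabet, alpha = alpha,
                              mode = mode, log_base = log_base)
    dplyr::mutate(tr, trial_id = id, .before = 1L)
  })
}
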