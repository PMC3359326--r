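#' Stimulus-design generators
#'
#' Reconstruct the two session designs used in the looking-time experiments:
#' single-box trials whose reveals are present/absent with a fixed
#' probability-of-appearance, and three-box trials whose reveals are draws
#' from a probability triple over three box-object pairs. All generation is
#' reproducible from a seed.
#'
#' @name stimulus_design
NULL

EXP1_ALPHABET <- c("present", "absent")
EXP2_ALPHABET <- c("A", "B", "C")
EVENT_DURATION_S <- 2
TIMEOUT_S <- 60
MAX_EVENTS <- TIMEOUT_S %/% EVENT_DURATION_S  # 30

#' Alphabet for a session design
#'
#' @param design A session design tibble.
#' @return Character vector of symbols: `present`/`absent` for the single-box
#'   experiment, `A`/`B`/`C` for the three-box experiment.
#' @export
design_alphabet <- function(design) {
  if (design$experiment[1] == 1) EXP1_ALPHABET else EXP2_ALPHABET
}

#' Generate one single-box event sequence
#'
#' The first reveal always shows the object; each subsequent reveal shows it
#' independently with probability `p`.
#'
#' @param p Probability-of-appearance in \[0, 1\].
#' @param length Number of events (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return Character vector of `"present"` / `"absent"` symbols.
#' @examples
#' generate_exp1_sequence(0.5, 10, seed = 1)
#' @export
generate_exp1_sequence <- function(p, length, seed = NULL) {
  check_probability(p)
  length <- check_count(length, "length")
  with_seed_if(seed, {
    rest <- if (length > 1L) {
      ifelse(runif(length - 1L) < p, "present", "absent")
    } else {
      character(0)
    }
    c("present", rest)
  })
}

#' Generate one three-box event sequence
#'
#' @param probs Probability triple (one entry per box-object pair) summing
#'   to 1.
#' @param length Number of events (>= 1).
#' @param seed Optional integer seed.
#' @return Character vector of `"A"` / `"B"` / `"C"` symbols.
#' @export
generate_exp2_sequence <- function(probs, length, seed = NULL) {
  check_triple(probs)
  length <- check_count(length, "length")
  with_seed_if(seed, {
    sample(EXP2_ALPHABET, size = length, replace = TRUE, prob = probs)
  })
}

check_triple <- function(probs) {
  if (!is.numeric(probs) || length(probs) != 3L) {
    abort("`probs` must be a numeric triple.")
  }
  check_probability(probs, "probs")
  if (abs(sum(probs) - 1) > 1e-9) {
    abort("`probs` must sum to 1 (within 1e-9).")
  }
  invisible(probs)
}

#' Generate a full single-box session (42 trials)
#'
#' The 21 probabilities-of-appearance 0, 0.05, ..., 1 each occur twice,
#' giving 42 trials, presented in a seed-shuffled order. Sequences are
#' pre-generated to the 30-event cap implied by the 60 s timeout at 2 s per
#' event.
#'
#' @param seed Optional integer seed.
#' @return A tibble with one row per trial: `trial_id` (presentation order),
#'   `experiment`, `generating_p`, `event_duration_s` and an `events`
#'   list-column of length-30 symbol vectors.
#' @export
generate_exp1_session <- function(seed = NULL) {
  p_grid <- rep(seq(0, 1, by = 0.05), times = 2)
  with_seed_if(seed, {
    p_shuffled <- sample(p_grid)
    tibble(
      trial_id = seq_along(p_shuffled),
      experiment = 1L,
      generating_p = p_shuffled,
      event_duration_s = EVENT_DURATION_S,
      events = purrr::map(p_shuffled, generate_exp1_sequence, length = MAX_EVENTS)
    )
  })
}

#' Default grid of 32 three-box generating distributions
#'
#' The original three-box study used 32 fixed event sequences whose
#' generating triples were not published; this grid is a synthetic stand-in
#' spanning degenerate (single-object), strongly skewed, moderately skewed
#' and uniform distributions. Replace it via the `distribution_grid` argument
#' of [generate_exp2_session()] to study other designs.
#'
#' @return A 32 x 3 numeric matrix with rows summing to 1.
#' @export
default_exp2_grid <- function() {
  perms <- function(x) unique(t(apply(perm3, 1, function(i) x[i])))
  base <- rbind(
    c(1, 0, 0),
    c(0.8, 0.2, 0),
    c(0.8, 0.1, 0.1),
    c(0.6, 0.3, 0.1),
    c(0.6, 0.2, 0.2),
    c(0.5, 0.4, 0.1),
    c(0.5, 0.25, 0.25)
  )
  grid <- do.call(rbind, lapply(seq_len(nrow(base)), function(i) perms(base[i, ])))
  grid <- grid[!duplicated(grid), , drop = FALSE]
  # 30 distinct permutations of the compositions above, plus a mildly skewed
  # triple and the uniform distribution = 32 trials
  grid <- rbind(grid, c(0.4, 0.35, 0.25), c(1, 1, 1) / 3)
  dimnames(grid) <- list(NULL, EXP2_ALPHABET)
  grid
}

perm3 <- rbind(
  c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)
)

#' Generate a full three-box session (32 trials)
#'
#' Each trial's sequence is drawn i.i.d. from its generating triple and
#' capped at 30 events; trial order is shuffled by the seed.
#'
#' @param seed Optional integer seed.
#' @param distribution_grid A 32 x 3 matrix (or list of 32 triples) of
#'   generating distributions, rows summing to 1. Defaults to
#'   [default_exp2_grid()].
#' @return A tibble with one row per trial: `trial_id`, `experiment`,
#'   `p_A`, `p_B`, `p_C`, `event_duration_s` and an `events` list-column.
#' @export
generate_exp2_session <- function(seed = NULL, distribution_grid = default_exp2_grid()) {
  if (is.list(distribution_grid)) {
    distribution_grid <- do.call(rbind, distribution_grid)
  }
  if (nrow(distribution_grid) != 32L) {
    abort("`distribution_grid` must contain exactly 32 distributions.")
  }
  apply(distribution_grid, 1, check_triple)
  with_seed_if(seed, {
    ord <- sample(nrow(distribution_grid))
    grid <- distribution_grid[ord, , drop = FALSE]
    tibble(
      trial_id = seq_len(nrow(grid)),
      experiment = 2L,
      p_A = grid[, 1], p_B = grid[, 2], p_C = grid[, 3],
      event_duration_s = EVENT_DURATION_S,
      events = purrr::map(seq_len(nrow(grid)), function(i) {
        generate_exp2_sequence(grid[i, ], length = MAX_EVENTS)
      })
    )
  })
}

#' Long (one row per event) view of a session design
#'
#' The flat form used for CSV interchange.
#'
#' @param design A session design tibble.
#' @return A tibble with `trial_id`, `experiment`, `event_index`, `symbol`
#'   and the trial's generating probabilities.
#' @export
design_events <- function(design) {
  out <- tidyr::unnest(
    dplyr::mutate(design, event_index = purrr::map(.data$events, seq_along)),
    c("events", "event_index")
  )
  dplyr::select(
    dplyr::rename(out, symbol = "events"),
    "trial_id", "experiment", "event_index", "symbol",
    dplyr::any_of(c("generating_p", "p_A", "p_B", "p_C"))
  )
}
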