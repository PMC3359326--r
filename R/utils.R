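# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed when one is supplied, leaving the
# caller's RNG stream untouched; with seed = NULL the current stream is used.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

# Population (divide-by-n) standard deviation.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# First TRUE per row of a logical matrix; NA_integer_ for all-FALSE rows.
first_true_idx <- function(m) {
  idx <- rep(NA_integer_, nrow(m))
  hits <- which(m, arr.ind = TRUE)
  if (nrow(hits) > 0L) {
    o <- order(hits[, 1L], hits[, 2L])
    keep <- !duplicated(hits[o, 1L])
    idx[hits[o, 1L][keep]] <- hits[o, 2L][keep]
  }
  idx
}

check_probability <- function(p, what = "p") {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1].", what))
  }
  invisible(p)
}

check_count <- function(n, what = "n", min = 1L) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < min || n != floor(n)) {
    abort(sprintf("`%s` must be a single integer >= %d.", what, min))
  }
  invisible(as.integer(n))
}
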