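#' Read and write pipeline configurations
#'
#' A [run_config()] round-trips through YAML unchanged, so a run is fully
#' described by a small text file plus the package version.
#'
#' @param config A [run_config()].
#' @param path File path for the YAML configuration.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(serialize_config(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  grid <- if (!is.null(raw$distribution_grid)) {
    do.call(rbind, raw$distribution_grid)
  } else {
    NULL
  }
  run_config(
    experiment = raw$experiment, seed = raw$seed, alpha = raw$alpha,
    mode = raw$mode,
    params = do.call(hazard_params, raw$params),
    n_infants = raw$n_infants, min_events = raw$min_events,
    n_bins = raw$n_bins, distribution_grid = grid
  )
}
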