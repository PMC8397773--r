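#' Run configuration
#'
#' Central container for the analysis settings shared across pipeline stages:
#' the association time window, the bounds of the nocturnal observation
#' period, permutation and seed settings, the logit clamp and an optional
#' rarefaction depth.
#'
#' @param window_minutes association time window in minutes; one of 720, 240,
#'   60, 30, 10, 2 (12 h down to 2 min).
#' @param night_start_hour,night_end_hour hour of day (0-23) at which a night
#'   starts on day *d* and ends on day *d + 1*; defaults 18 and 6 (6 pm-6 am).
#' @param n_permutations number of permutations for all permutation tests
#'   (at least 99).
#' @param seed integer random seed recorded in every manifest.
#' @param epsilon_logit clamp applied to proportions before the logit
#'   transform; must lie in (0, 0.01].
#' @param rarefaction_depth optional fixed rarefaction depth (reads); `NULL`
#'   lets [rarefy_community()] use its default.
#' @return A list of class `"run_config"`.
#' @export
#' @examples
#' run_config(window_minutes = 2, n_permutations = 199, seed = 42)
run_config <- function(window_minutes = 720, night_start_hour = 18,
                       night_end_hour = 6, n_permutations = 999, seed = 1,
                       epsilon_logit = 1e-6, rarefaction_depth = NULL) {
  allowed <- c(720, 240, 60, 30, 10, 2)
  if (!window_minutes %in% allowed) {
    abort(sprintf("`window_minutes` must be one of: %s",
                  paste(allowed, collapse = ", ")))
  }
  night_len <- night_length_minutes(night_start_hour, night_end_hour)
  if (window_minutes > night_len) {
    abort("`window_minutes` must not exceed the night length.")
  }
  if (n_permutations < 99) abort("`n_permutations` must be at least 99.")
  if (epsilon_logit <= 0 || epsilon_logit > 0.01) {
    abort("`epsilon_logit` must lie in (0, 0.01].")
  }
  structure(list(window_minutes = window_minutes,
                 night_start_hour = night_start_hour,
                 night_end_hour = night_end_hour,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 epsilon_logit = epsilon_logit,
                 rarefaction_depth = rarefaction_depth),
            class = "run_config")
}

night_length_minutes <- function(start_hour, end_hour) {
  ((24 - start_hour) + end_hour) * 60
}

#' Read a run configuration from YAML
#'
#' Fields absent from the file take the [run_config()] defaults; `overrides`
#' (e.g. parsed command-line flags) take precedence over the file.
#'
#' @param path YAML file path.
#' @param overrides named list of field overrides.
#' @return A `"run_config"` list.
#' @export
read_run_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals[names(vals) %in% names(formals(run_config))])
}

#' Write a JSON run manifest
#'
#' Every pipeline stage records its provenance (seed, window, permutation
#' count, stage-specific settings) so stochastic results are reproducible.
#'
#' @param path output JSON path.
#' @param ... named manifest fields.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, ...) {
  jsonlite::write_json(list(...), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
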