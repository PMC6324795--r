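# Plain-text configuration for scenarios and models --------------------------

#' Write an input-scenario configuration to a YAML file
#'
#' @param scenario One-row data frame (or named list) with `f_exc`, `f_inh`,
#'   `n_exc`, `n_inh`, and optionally `k_exc`, `k_inh`, `seed`, `variant`,
#'   `duration`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(scenario, path) {
  rlang::check_installed("yaml")
  fields <- c(
    "variant", "f_exc", "f_inh", "n_exc", "n_inh", "k_exc", "k_inh",
    "seed", "duration"
  )
  x <- as.list(scenario)[intersect(fields, names(scenario))]
  yaml::write_yaml(lapply(x, function(v) unname(v[[1]])), path)
  invisible(path)
}

#' Read an input-scenario configuration from a YAML file
#'
#' Fills defaults for any omitted field (`k_exc = k_inh = 1`, `seed = 1`,
#' `variant = "AType+"`, `duration = 10000`).
#'
#' @param path YAML file path.
#' @return One-row tibble with the scenario parameters.
#' @export
read_scenario_config <- function(path) {
  rlang::check_installed("yaml")
  x <- yaml::read_yaml(path)
  need <- c("f_exc", "f_inh", "n_exc", "n_inh")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(paste("scenario config lacks fields:", paste(missing, collapse = ", ")))
  }
  tibble::tibble(
    variant = x$variant %||% "AType+",
    f_exc = x$f_exc, f_inh = x$f_inh,
    n_exc = x$n_exc, n_inh = x$n_inh,
    k_exc = x$k_exc %||% 1, k_inh = x$k_inh %||% 1,
    seed = as.integer(x$seed %||% 1L),
    duration = x$duration %||% 10000
  )
}
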