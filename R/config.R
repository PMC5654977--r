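#' Read and write simulation configuration files
#'
#' Simulation parameters round-trip through structured YAML so runs can be
#' described by a single config file; unknown keys are rejected rather than
#' silently ignored.
#'
#' @param path YAML file path.
#' @param params A [sim_params()] object.
#' @return `read_sim_config()` returns a `sim_params`; `write_sim_config()`
#'   returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    abort("config files need the yaml package")
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_params))
  extra <- setdiff(names(vals), known)
  if (length(extra))
    abort(sprintf("unknown config keys: %s", paste(extra, collapse = ", ")))
  do.call(sim_params, vals)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(params, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    abort("config files need the yaml package")
  stopifnot(inherits(params, "sim_params"))
  yaml::write_yaml(unclass(params), path, precision = 15)
  invisible(path)
}
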