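# Structured text (YAML) configuration round trip for sweep runs.

#' Write a sweep configuration to a YAML file
#'
#' @param config A `dot_sweep_config`.
#' @param path Output file path.
#' @export
write_config <- function(config, path) {
  plain <- rapply(unclass(config), unclass, how = "replace")
  # data.frames (noise coefficients) serialize as column lists
  plain$noise$params <- as.list(config$noise$params)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Read a sweep configuration from a YAML file
#'
#' Values found in the file override the package defaults from
#' [sweep_config()]; anything not present keeps its default.
#'
#' @param path YAML file path.
#' @return A `dot_sweep_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$noise$params)) {
    raw$noise$params <- as.data.frame(raw$noise$params)
  }
  if (!is.null(raw$phantom$layer_thicknesses)) {
    raw$phantom$layer_thicknesses <- unlist(raw$phantom$layer_thicknesses)
  }
  if (!is.null(raw$perturbation)) raw$perturbation <- unlist(raw$perturbation)
  do.call(sweep_config, raw)
}
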