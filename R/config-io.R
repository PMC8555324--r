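#' Read / write a run configuration as YAML
#'
#' The configuration file has `beamline`, `perturbations` and `detector`
#' sections mirroring [beamline_config()], [gantry_perturbation()] and the
#' detector specs.
#'
#' @param path YAML file path.
#' @return For `read_run_config`: list with `beamline` (a
#'   [beamline_config()]), `perturbations` (named list of
#'   [gantry_perturbation()]) and `detector`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- list()
  out$beamline <- do.call(beamline_config, raw$beamline %||% list())
  out$perturbations <- if (is.null(raw$perturbations)) {
    default_gantry_perturbations()
  } else {
    lapply(raw$perturbations, function(p) do.call(gantry_perturbation, p))
  }
  out$detector <- raw$detector %||% lynx_detector()
  out
}

#' @rdname read_run_config
#' @param config List as returned by `read_run_config`.
#' @export
write_run_config <- function(config, path) {
  strip <- function(x) { attributes(x) <- list(names = names(x)); x }
  yaml::write_yaml(list(
    beamline = strip(config$beamline),
    perturbations = lapply(config$perturbations, strip),
    detector = config$detector
  ), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
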