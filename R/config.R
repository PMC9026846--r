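#' Read a run configuration file
#'
#' Reads a YAML or JSON configuration holding parameter overrides for the
#' detectors, the wavelet transform, micro-arousal classification and the
#' simulator, plus I/O settings such as the sampling rate of headerless text
#' input. Recognized top-level sections: `fs`, `wavelet`, `swd`, `sleep`,
#' `microarousal`, `simulation`. Unknown keys inside a section are an error
#' (they usually mean a typo in a parameter name).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list of configuration sections.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("cannot read config: ", path)
  cfg <- if (grepl("json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- c("fs", "wavelet", "swd", "sleep", "microarousal", "simulation")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "))
  cfg
}

# apply a named override list onto a params constructor, rejecting unknown
# or type-incompatible keys
.params_with <- function(constructor, overrides) {
  if (is.null(overrides) || !length(overrides)) return(constructor())
  defaults <- formals(constructor)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  do.call(constructor, overrides)
}

#' Materialize parameter objects from a configuration list
#'
#' Turns the sections of [read_run_config()] output into the corresponding
#' parameter objects, applying defaults for anything not overridden.
#'
#' @param cfg list as returned by [read_run_config()] (may be empty).
#' @return List with elements `wavelet`, `swd`, `sleep`, `ma`, `simulation`,
#'   `fs`.
#' @export
params_from_config <- function(cfg) {
  list(wavelet = .params_with(wavelet_config, cfg$wavelet),
       swd = .params_with(swd_detector_params, cfg$swd),
       sleep = .params_with(sleep_detector_params, cfg$sleep),
       ma = .params_with(microarousal_params, cfg$microarousal),
       simulation = .params_with(simulation_config, cfg$simulation),
       fs = cfg$fs)
}
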