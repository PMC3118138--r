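# Trajectory and manifest I/O.

#' Write a trajectory as tidy CSV
#'
#' One row per accepted step: `time_h`, `temperature_C`, `biomass_gDW_L`,
#' one column per tracked species, and the per-step diagnostics (phase,
#' growth rate, maintenance bound, carbohydrate fraction).
#'
#' @param traj a `trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  write.csv(traj$states, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory table written by [write_trajectory()]
#' @param path CSV path.
#' @return data.frame of states.
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop_dynafba("dynafba_io_error", "file not found: ", path)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read a tidy experimental dataset
#'
#' Expects columns `time_h`, `species`, `value` (a `unit` column is allowed
#' and ignored for scoring).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_experiment <- function(path) {
  if (!file.exists(path)) stop_dynafba("dynafba_io_error", "file not found: ", path)
  ex <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "species", "value")
  if (!all(need %in% names(ex)))
    stop_dynafba("dynafba_schema_error", "experiment CSV needs columns: ",
                 paste(need, collapse = ", "))
  ex
}

#' Run manifest
#'
#' Collects everything needed to reproduce a run bit-identically: the
#' configuration, the model checksum, the modification list, the solver
#' backend and the package version, plus the termination reason.
#'
#' @param traj a `trajectory`.
#' @param model_path path of the model file used (checksummed when it
#'   exists).
#' @param mods_path optional modification file path.
#' @return a list (serialisable with [jsonlite::write_json()]).
#' @export
run_manifest <- function(traj, model_path = NULL, mods_path = NULL) {
  cfg <- traj$metadata$config
  cfg_ser <- cfg
  cfg_ser$kinetics <- unclass(cfg$kinetics)
  cfg_ser$composition <- unclass(cfg$composition)
  list(
    package = "dynafba",
    package_version = traj$metadata$package_version,
    solver = traj$metadata$solver,
    model_path = model_path,
    model_md5 = if (!is.null(model_path) && file.exists(model_path))
      unname(tools::md5sum(model_path)) else NULL,
    modifications = mods_path,
    config = unclass(cfg_ser),
    initial = list(temperature = traj$initial$temperature,
                   biomass = traj$initial$biomass,
                   concentrations = traj$initial$conc),
    termination = traj$termination,
    steps = nrow(traj$states),
    final_time_h = traj$states$time_h[nrow(traj$states)])
}
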