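#' Read and write network configurations as JSON
#'
#' Every field is explicit, seeds included, so a written configuration
#' reproduces its runs exactly.
#'
#' @param config a [network_config()].
#' @param path file path.
#' @return `write_network_config` returns the path invisibly;
#'   `read_network_config` returns a validated `network_config`.
#' @export
write_network_config <- function(config, path) {
  stopifnot(inherits(config, "network_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_network_config
#' @export
read_network_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(network_config, raw)
}

#' Write a spike raster as CSV
#'
#' Columns `neuron_id` (0-based), `population`, `time_ms`.
#'
#' @param raster raster data.frame from [simulate_network()].
#' @param path file path.
#' @export
write_raster_csv <- function(raster, path) {
  write.csv(raster[, c("neuron_id", "population", "time_ms")], path,
            row.names = FALSE)
  invisible(path)
}

#' Write interneuron voltage traces as CSV
#'
#' `time_ms` column followed by one column per interneuron (`v<neuron_id>`).
#'
#' @param traces `voltage_traces` object.
#' @param path file path.
#' @export
write_traces_csv <- function(traces, path) {
  stopifnot(inherits(traces, "voltage_traces"))
  df <- data.frame(time_ms = traces$time_ms, traces$v)
  names(df)[-1] <- paste0("v", traces$neuron_ids)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a phase series as CSV (radians) with a JSON filter sidecar
#'
#' @param phases `phase_series` object.
#' @param path CSV path; the filter specification (if any) is written next to
#'   it as `<path>.json`.
#' @export
write_phases_csv <- function(phases, path) {
  stopifnot(inherits(phases, "phase_series"))
  df <- data.frame(time_ms = phases$time_ms, phases$phi)
  names(df)[-1] <- paste0("phi", phases$neuron_ids)
  write.csv(df, path, row.names = FALSE)
  if (!is.null(phases$filter)) {
    jsonlite::write_json(unclass(phases$filter), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write a frequency sweep (or connectivity grid / CR curves) as tidy CSV
#'
#' @param x data.frame result from one of the experiment drivers.
#' @param path file path.
#' @export
write_experiment_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
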