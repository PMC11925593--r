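# Config, trace and report I/O. All configs share one YAML dialect with a
# top-level `type` field; traces and calibration samples are plain CSV
# with a mandatory header, '.' decimal separator, UTF-8.

read_config_typed <- function(path, type) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path), class = "pcrtwin_missing_file")
  }
  cfg <- yaml::read_yaml(path)
  if (!identical(cfg$type, type)) {
    abort(sprintf("Expected a '%s' config in %s, found type '%s'.",
                  type, path, cfg$type %||% "<none>"))
  }
  cfg
}

#' Read and write sensor configuration files
#'
#' A sensor config stores the calibration line, the noise level and the
#' ADC geometry:
#' ```yaml
#' type: sensor
#' a_mV: 19.5
#' b_mV_per_C: 10.14
#' noise_sd_C: 0.08
#' adc:
#'   reference_voltage_mV: 5000
#'   bits: 10
#' ```
#'
#' @param path File path.
#' @return `read_sensor_config()` returns a list with `cal`
#'   (a [sensor_calibration()]), `noise_sd_C`, and `adc`
#'   (an [adc_config()]).
#' @export
read_sensor_config <- function(path) {
  cfg <- read_config_typed(path, "sensor")
  list(
    cal = sensor_calibration(cfg$a_mV, cfg$b_mV_per_C),
    noise_sd_C = cfg$noise_sd_C %||% 0,
    adc = adc_config(cfg$adc$reference_voltage_mV %||% 5000,
                     cfg$adc$bits %||% 10L)
  )
}

#' @rdname read_sensor_config
#' @param cal A [sensor_calibration()].
#' @param noise_sd_C Gaussian sensor noise, degC.
#' @param adc An [adc_config()].
#' @return `write_sensor_config()` returns `path`, invisibly.
#' @export
write_sensor_config <- function(cal, path, noise_sd_C = 0.08,
                                adc = adc_config()) {
  stopifnot(inherits(cal, "sensor_calibration"))
  yaml::write_yaml(list(
    type = "sensor",
    a_mV = cal$a_mV, b_mV_per_C = cal$b_mV_per_C,
    noise_sd_C = noise_sd_C,
    adc = list(reference_voltage_mV = adc$reference_voltage_mV,
               bits = adc$bits)
  ), path, precision = 15)
  invisible(path)
}

#' Read and write plant configuration files
#'
#' @param path File path.
#' @return `read_plant_config()` returns a [plant_params()].
#' @export
read_plant_config <- function(path) {
  cfg <- read_config_typed(path, "plant")
  plant_params(cfg$gain_heat_C_per_s, cfg$gain_cool_C_per_s,
               cfg$loss_coeff_per_s, cfg$ambient_C %||% 25)
}

#' @rdname read_plant_config
#' @param params A [plant_params()].
#' @return `write_plant_config()` returns `path`, invisibly.
#' @export
write_plant_config <- function(params, path) {
  stopifnot(inherits(params, "plant_params"))
  yaml::write_yaml(list(
    type = "plant",
    gain_heat_C_per_s = params$gain_heat_C_per_s,
    gain_cool_C_per_s = params$gain_cool_C_per_s,
    loss_coeff_per_s = params$loss_coeff_per_s,
    ambient_C = params$ambient_C,
    max_pwm = params$max_pwm
  ), path, precision = 15)
  invisible(path)
}

#' Read and write protocol files
#'
#' A protocol file lists the bracket stages, the cycled block and the
#' cycle count, plus the lid setpoint and optional per-stage gain
#' overrides (applied with [default_gain_schedule()]).
#'
#' @param path File path.
#' @return `read_protocol()` returns a list with `protocol`
#'   (a [pcr_protocol()]) and `schedule` (a gain schedule with any
#'   overrides applied).
#' @export
read_protocol <- function(path) {
  cfg <- read_config_typed(path, "protocol")
  as_stage <- function(kind, x) protocol_stage(kind, x$target_C, x$hold_s)
  cycle <- purrr::map(cfg$cycle, function(x) as_stage(x$kind, x))
  protocol <- pcr_protocol(
    initial_denaturation = as_stage("initial_denaturation",
                                    cfg$initial_denaturation),
    cycle_block = cycle,
    cycles = cfg$cycles,
    final_extension = as_stage("final_extension", cfg$final_extension),
    lid_setpoint_C = cfg$lid_setpoint_C %||% 105
  )
  list(protocol = protocol,
       schedule = default_gain_schedule(cfg$gain_overrides))
}

#' @rdname read_protocol
#' @param protocol A [pcr_protocol()].
#' @param gain_overrides Optional overrides stored with the protocol.
#' @return `write_protocol()` returns `path`, invisibly.
#' @export
write_protocol <- function(protocol, path, gain_overrides = NULL) {
  stopifnot(inherits(protocol, "pcr_protocol"))
  st <- function(x) list(kind = x$kind, target_C = x$target_C, hold_s = x$hold_s)
  out <- list(
    type = "protocol",
    lid_setpoint_C = protocol$lid_setpoint_C,
    initial_denaturation = st(protocol$initial_denaturation),
    cycle = purrr::map(protocol$cycle_block, st),
    cycles = protocol$cycles,
    final_extension = st(protocol$final_extension)
  )
  if (!is.null(gain_overrides)) out$gain_overrides <- gain_overrides
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Read and write temperature traces as CSV
#'
#' The trace CSV has a mandatory header and starts with the columns
#' `time_s, block_true_C, block_measured_C, lid_C, pwm, direction,
#' stage_label, cycle_index`, followed by the remaining trace columns.
#'
#' @param trace A `pcr_trace`.
#' @param path File path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()`
#'   returns a `pcr_trace` tibble.
#' @export
write_trace <- function(trace, path) {
  trace <- as_pcr_trace(trace)
  lead <- c("time_s", "block_true_C", "block_measured_C", "lid_C", "pwm",
            "direction", "stage_label", "cycle_index")
  lead <- intersect(lead, names(trace))
  trace <- trace[, c(lead, setdiff(names(trace), lead))]
  readr::write_csv(trace, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Trace file not found: %s", path), class = "pcrtwin_missing_file")
  }
  tr <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_pcr_trace(tr)
}

#' Read and write calibration sample sets
#'
#' Two-column CSV (`true_temp_C`, `vout_mV`) with a header row.
#'
#' @param samples A data frame with `true_temp_C` and `vout_mV`.
#' @param path File path.
#' @export
write_calibration_samples <- function(samples, path) {
  stopifnot(all(c("true_temp_C", "vout_mV") %in% names(samples)))
  readr::write_csv(as_tibble(samples)[, c("true_temp_C", "vout_mV")], path,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_calibration_samples
#' @export
read_calibration_samples <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Calibration sample file not found: %s", path),
          class = "pcrtwin_missing_file")
  }
  s <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("true_temp_C", "vout_mV") %in% names(s))) {
    abort("Calibration CSV needs columns `true_temp_C` and `vout_mV`.")
  }
  s
}

#' Write a performance report
#'
#' Writes the report both as machine-readable JSON (`<path>.json`) and as
#' human-readable text (`<path>.txt`).
#'
#' @param report A [performance_report()].
#' @param path Output path prefix (without extension).
#' @return Character vector of the two file paths, invisibly.
#' @export
write_performance_report <- function(report, path) {
  stopifnot(inherits(report, "performance_report"))
  json_path <- paste0(path, ".json")
  txt_path <- paste0(path, ".txt")
  jsonlite::write_json(
    list(ramps = report$ramps, holds = report$holds,
         lid = report$lid, checks = report$checks),
    json_path, dataframe = "rows", auto_unbox = TRUE, digits = NA, null = "null"
  )
  txt <- utils::capture.output(print(report))
  writeLines(txt, txt_path)
  invisible(c(json_path, txt_path))
}

#' Build a run manifest
#'
#' Every simulation output is accompanied by a manifest recording the
#' inputs, the resolved seed and the tool version.
#'
#' @param inputs Named list or character vector of input file paths.
#' @param outputs Character vector of output paths.
#' @param seed Integer seed used for the run.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(inputs = character(), outputs = character(),
                         seed = NA_integer_) {
  structure(list(
    tool = "pcrtwin",
    version = as.character(packageVersion("pcrtwin")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    inputs = as.list(inputs),
    outputs = as.list(outputs)
  ), class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest A `run_manifest`.
#' @param path Output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Path to a packaged reference file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a vector of file names).
#' @examples
#' pcrtwin_extdata()
#' @export
pcrtwin_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "pcrtwin")))
  }
  path <- system.file("extdata", file, package = "pcrtwin")
  if (path == "") abort(sprintf("No packaged file '%s'.", file))
  path
}

#' Packaged reference models
#'
#' The reference block plant was produced by [fit_plant_to_observables()]
#' against the instrument's printed ramp observables
#' ([reference_ramp_targets()]); the reference lid plant represents the
#' 14 W PTC lid heater, with its loss coefficient set so the unregulated
#' equilibrium matches the element's ~220 degC dry-firing surface
#' temperature. Both are stored as plain-text configs under `extdata` and
#' can be regenerated with [make_reference_configs()].
#'
#' @return A [plant_params()].
#' @export
reference_block_params <- function() {
  read_plant_config(pcrtwin_extdata("reference_block.yaml"))
}

#' @rdname reference_block_params
#' @export
reference_lid_params <- function() {
  read_plant_config(pcrtwin_extdata("reference_lid.yaml"))
}
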