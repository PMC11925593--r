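#' Generate a calibration sample set
#'
#' Emits water-bath-style calibration samples from the linear sensor law
#' `vout = b * T - a`, optionally with Gaussian voltage noise and ADC
#' quantization. The packaged noiseless fixture uses the reference line
#' (a = 19.50, b = 10.14) on a 30-100 degC grid in 5 degC steps.
#'
#' @param a_mV,b_mV_per_C True sensor line used to generate the samples.
#' @param grid_C Grid of bath temperatures.
#' @param noise_sd_C Gaussian noise standard deviation, degC equivalent
#'   (0 gives exactly collinear samples).
#' @param n_per_point Samples recorded per grid temperature.
#' @param seed Integer seed.
#' @param quantize Whether the ADC quantizes the recorded voltages.
#' @param adc An [adc_config()] (used when `quantize = TRUE`).
#' @param path Optional CSV output path (see
#'   [write_calibration_samples()]).
#' @return A tibble with `true_temp_C` and `vout_mV`.
#' @examples
#' fit_calibration(make_calibration_fixture(noise_sd_C = 0, quantize = FALSE))
#' @export
make_calibration_fixture <- function(a_mV = 19.50, b_mV_per_C = 10.14,
                                     grid_C = seq(30, 100, by = 5),
                                     noise_sd_C = 0, n_per_point = 1,
                                     seed = 1L, quantize = FALSE,
                                     adc = adc_config(), path = NULL) {
  if (length(grid_C) == 0) abort("`grid_C` must not be empty.")
  cal <- sensor_calibration(a_mV, b_mV_per_C)
  withr::local_seed(seed)
  tt <- rep(grid_C, each = n_per_point)
  v <- temp_to_voltage(tt, cal)
  if (noise_sd_C > 0) v <- v + rnorm(length(v), 0, noise_sd_C * b_mV_per_C)
  if (quantize) v <- adc_quantize(v, adc)
  samples <- tibble(true_temp_C = tt, vout_mV = v)
  if (!is.null(path)) write_calibration_samples(samples, path)
  samples
}

#' Analytic traces with known closed-form metrics
#'
#' Three constructed traces for validating the metrics module against
#' closed forms: a linear 55 to 95 degC ramp over 20 s (average and
#' maximum rate exactly 2 degC/s), a sinusoidal hold around 72 degC with
#' amplitude 0.5 degC and a 4 s period (maximum absolute hold error
#' exactly 0.5 degC, mean ~0), and a triangular lid wave between 104 and
#' 106 degC (maximum deviation from 105 exactly 1 degC).
#'
#' @param dt Sampling step, seconds.
#' @param dir Optional directory: if given, each trace is also written as
#'   `analytic_<name>.csv`.
#' @return A named list of `pcr_trace` tibbles (`linear`, `sine`,
#'   `triangle`).
#' @export
make_analytic_traces <- function(dt = 0.1, dir = NULL) {
  base_cols <- function(t, temp, label, kind, target, phase) {
    tibble(
      time_s = t, block_true_C = temp, block_measured_C = temp,
      lid_C = NA_real_, pwm = 0L, direction = "idle",
      stage_label = label, cycle_index = 0L, stage_index = 1L,
      kind = kind, target_C = target, phase = phase
    )
  }
  t_lin <- seq(0, 20, by = dt)
  linear <- base_cols(t_lin, 55 + 2 * t_lin, "001_denaturation",
                      "denaturation", 95, "ramp")
  t_sin <- seq(0, 61, by = dt)
  sine <- base_cols(t_sin, 72 + 0.5 * sin(2 * pi * t_sin / 4),
                    "001_extension", "extension", 72, "hold")
  t_tri <- seq(0, 60, by = dt)
  triangle <- base_cols(t_tri, 105, "001_extension", "extension", 72, "hold")
  triangle$lid_C <- 105 + (2 / pi) * asin(sin(2 * pi * t_tri / 4))
  out <- list(linear = as_pcr_trace(linear), sine = as_pcr_trace(sine),
              triangle = as_pcr_trace(triangle))
  if (!is.null(dir)) {
    for (nm in names(out)) {
      write_trace(out[[nm]], file.path(dir, sprintf("analytic_%s.csv", nm)))
    }
  }
  out
}

#' Regenerate the packaged reference configurations
#'
#' Re-derives every packaged reference file from first principles:
#' the block plant by running [fit_plant_to_observables()] against the
#' printed ramp observables, the lid plant from its design constants
#' (0.8 degC/s full-drive gain; loss coefficient 0.8/195 per s so the
#' unregulated equilibrium is the element's ~220 degC dry-firing
#' temperature), the reference sensor line, the 30-cycle protocol, and
#' the noiseless calibration fixture. The derivation is deterministic, so
#' regeneration is idempotent.
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written file paths; the fitted
#'   block model is attached as attribute `"block_fit"`.
#' @export
make_reference_configs <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  block <- fit_plant_to_observables()
  lid <- plant_params(0.8, 0.8, 0.8 / 195, ambient_C = 25)
  paths <- list(
    block = file.path(dir, "reference_block.yaml"),
    lid = file.path(dir, "reference_lid.yaml"),
    sensor = file.path(dir, "reference_sensor.yaml"),
    protocol = file.path(dir, "protocol_30cycle.yaml"),
    calibration = file.path(dir, "calibration_noiseless.csv")
  )
  write_plant_config(block, paths$block)
  write_plant_config(lid, paths$lid)
  write_sensor_config(sensor_calibration(), paths$sensor, noise_sd_C = 0.08)
  write_protocol(pcr_protocol(), paths$protocol)
  make_calibration_fixture(path = paths$calibration)
  attr(paths, "block_fit") <- block
  invisible(paths)
}
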