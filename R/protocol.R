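#' A single PCR protocol stage
#'
#' @param kind Stage kind: one of `"initial_denaturation"`,
#'   `"denaturation"`, `"annealing"`, `"extension"`, `"final_extension"`.
#' @param target_C Stage target temperature, degC.
#' @param hold_s Hold duration at the target, seconds (> 0). The hold
#'   timer starts when the measured temperature first enters the
#'   hold-entry band around the target.
#' @return A `protocol_stage` list.
#' @examples
#' protocol_stage("annealing", 55, 15)
#' @export
protocol_stage <- function(kind, target_C, hold_s) {
  kinds <- c("initial_denaturation", "denaturation", "annealing",
             "extension", "final_extension")
  if (!is.character(kind) || length(kind) != 1 || !kind %in% kinds) {
    abort(sprintf("`kind` must be one of: %s", paste(kinds, collapse = ", ")))
  }
  stopifnot_number(target_C, "target_C")
  stopifnot_number(hold_s, "hold_s", 0, strict = TRUE)
  structure(list(kind = kind, target_C = target_C, hold_s = hold_s),
            class = "protocol_stage")
}

#' Define a PCR thermal-cycling protocol
#'
#' A protocol is an initial denaturation, a cycled block of
#' denaturation / annealing / extension stages, and a final extension,
#' plus the heated-lid setpoint. The defaults are the packaged reference
#' protocol: 30 cycles of 95 degC / 15 s, 55 degC / 15 s, 72 degC / 60 s,
#' bracketed by a 180 s initial denaturation and a 300 s final extension
#' (conventional bracket durations), with the lid at 105 degC.
#'
#' @param initial_denaturation,final_extension [protocol_stage()]s.
#' @param cycle_block List of [protocol_stage()]s repeated each cycle.
#' @param cycles Number of cycles (>= 0).
#' @param lid_setpoint_C Heated-lid setpoint, degC.
#' @return A `pcr_protocol` object.
#' @examples
#' pcr_protocol(cycles = 2)
#' @export
pcr_protocol <- function(initial_denaturation = protocol_stage("initial_denaturation", 95, 180),
                         cycle_block = list(
                           protocol_stage("denaturation", 95, 15),
                           protocol_stage("annealing", 55, 15),
                           protocol_stage("extension", 72, 60)
                         ),
                         cycles = 30L,
                         final_extension = protocol_stage("final_extension", 72, 300),
                         lid_setpoint_C = 105) {
  stopifnot(inherits(initial_denaturation, "protocol_stage"),
            inherits(final_extension, "protocol_stage"))
  if (!is_number(cycles) || cycles < 0 || cycles != as.integer(cycles)) {
    abort("`cycles` must be a non-negative whole number.")
  }
  ok <- all(vapply(cycle_block, inherits, logical(1), "protocol_stage"))
  if (!ok) abort("`cycle_block` must be a list of protocol_stage objects.")
  stopifnot_number(lid_setpoint_C, "lid_setpoint_C")
  structure(
    list(initial_denaturation = initial_denaturation,
         cycle_block = cycle_block, cycles = as.integer(cycles),
         final_extension = final_extension,
         lid_setpoint_C = lid_setpoint_C),
    class = "pcr_protocol"
  )
}

#' @export
print.pcr_protocol <- function(x, ...) {
  cat(sprintf("<pcr_protocol> %d cycles, lid %g degC\n", x$cycles,
              x$lid_setpoint_C))
  print(expand_protocol(x), n = 5)
  invisible(x)
}

#' Expand a protocol into its ordered stage sequence
#'
#' @param protocol A [pcr_protocol()].
#' @return A tibble with one row per executed stage: `stage_index`,
#'   `stage_label` (unique), `kind`, `target_C`, `hold_s` and
#'   `cycle_index` (0 for the initial denaturation, 1..cycles inside the
#'   cycled block, cycles + 1 for the final extension). Its length is
#'   `2 + 3 * cycles` for the standard three-stage cycle block.
#' @examples
#' nrow(expand_protocol(pcr_protocol(cycles = 30))) # 92
#' @export
expand_protocol <- function(protocol) {
  stopifnot(inherits(protocol, "pcr_protocol"))
  rows <- list(c(protocol$initial_denaturation, cycle_index = 0L))
  for (cy in seq_len(protocol$cycles)) {
    for (st in protocol$cycle_block) {
      rows <- c(rows, list(c(st, cycle_index = cy)))
    }
  }
  rows <- c(rows, list(c(protocol$final_extension,
                         cycle_index = protocol$cycles + 1L)))
  out <- purrr::map_dfr(rows, function(r) {
    tibble(kind = r$kind, target_C = r$target_C, hold_s = r$hold_s,
           cycle_index = r$cycle_index)
  })
  out$stage_index <- seq_len(nrow(out))
  out$stage_label <- sprintf("%03d_%s", out$stage_index, out$kind)
  out[, c("stage_index", "stage_label", "kind", "target_C", "hold_s",
          "cycle_index")]
}

#' Heated-lid on/off thermostat
#'
#' The heated lid has no PID or PWM regulation: a hysteresis (bang-bang)
#' thermostat switches the full 14 W drive on below
#' `setpoint - band/2` and off above `setpoint + band/2`, and keeps its
#' previous state inside the band.
#'
#' @param setpoint_C Lid setpoint, degC (105 by default).
#' @param hysteresis_band_C Full width of the hysteresis band, degC.
#' @return A `lid_thermostat` object.
#' @export
lid_thermostat <- function(setpoint_C = 105, hysteresis_band_C = 2) {
  stopifnot_number(setpoint_C, "setpoint_C")
  stopifnot_number(hysteresis_band_C, "hysteresis_band_C", 0, strict = TRUE)
  structure(list(setpoint_C = setpoint_C,
                 hysteresis_band_C = hysteresis_band_C),
            class = "lid_thermostat")
}

#' One thermostat decision
#'
#' @param thermostat A [lid_thermostat()].
#' @param lid_temp_C Current (measured) lid temperature, degC.
#' @param on Current drive state (logical).
#' @return The new drive state: `TRUE` (full drive) or `FALSE` (off).
#' @examples
#' lid_step(lid_thermostat(105, 2), 20, FALSE)  # TRUE: heat up
#' lid_step(lid_thermostat(105, 2), 107, TRUE)  # FALSE: too hot
#' @export
lid_step <- function(thermostat, lid_temp_C, on = FALSE) {
  stopifnot(inherits(thermostat, "lid_thermostat"))
  lo <- thermostat$setpoint_C - thermostat$hysteresis_band_C / 2
  hi <- thermostat$setpoint_C + thermostat$hysteresis_band_C / 2
  if (lid_temp_C < lo) TRUE else if (lid_temp_C > hi) FALSE else on
}

#' Simulation configuration
#'
#' Timing, sensor-noise and engine settings for [run_protocol()].
#'
#' @param dt Plant integration and trace sampling step, seconds (0.1 s;
#'   `dt * loss_coeff` stays far below the explicit-Euler stability
#'   limit).
#' @param control_period_s Controller (and lid thermostat) update period,
#'   seconds; must be a multiple of `dt`. The PWM command is held between
#'   updates. Default 0.2 s; see the vignette for how this interacts with
#'   the raw-sum PID gains.
#' @param seed Integer seed; every random draw in a simulation derives
#'   from it, so traces are bit-reproducible.
#' @param start_temp_C Initial block temperature (default 26.39 degC, the
#'   reference instrument's recorded room-temperature start).
#' @param lid_start_temp_C Initial lid temperature; defaults to the lid
#'   plant's ambient.
#' @param noise_sd_C Sensor Gaussian noise, degC equivalent.
#' @param quantize Whether the ADC quantizes measurements.
#' @param adc_oversample Number of ADC conversions averaged per controller
#'   measurement (25 by default). Oversampling is standard practice on
#'   this class of microcontroller firmware: it suppresses measurement
#'   noise and dithers the quantization staircase, so the closed loop
#'   tracks its noiseless behaviour closely. Single readings (as logged
#'   or used for calibration checks) are not averaged.
#' @param hold_entry_band_C A stage's hold timer starts when the measured
#'   temperature first comes within this band of the target (1 degC).
#' @param stall_timeout_s If a stage has not entered its hold band after
#'   this long, the run aborts with a stalled-protocol error.
#' @param sep_band_C PID integral separation band (see [pid_step()]).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(dt = 0.1, control_period_s = 0.2, seed = 1L,
                              start_temp_C = 26.39, lid_start_temp_C = NULL,
                              noise_sd_C = 0.08, quantize = TRUE,
                              adc_oversample = 25L,
                              hold_entry_band_C = 1, stall_timeout_s = 300,
                              sep_band_C = 2) {
  stopifnot_number(adc_oversample, "adc_oversample", 1)
  stopifnot_number(dt, "dt", 0, strict = TRUE)
  stopifnot_number(control_period_s, "control_period_s", 0, strict = TRUE)
  ratio <- control_period_s / dt
  if (abs(ratio - round(ratio)) > 1e-8 || round(ratio) < 1) {
    abort("`control_period_s` must be a positive multiple of `dt`.")
  }
  stopifnot_number(noise_sd_C, "noise_sd_C", 0)
  stopifnot_number(hold_entry_band_C, "hold_entry_band_C", 0, strict = TRUE)
  stopifnot_number(stall_timeout_s, "stall_timeout_s", 0, strict = TRUE)
  structure(
    list(dt = dt, control_period_s = control_period_s,
         seed = as.integer(seed), start_temp_C = start_temp_C,
         lid_start_temp_C = lid_start_temp_C, noise_sd_C = noise_sd_C,
         quantize = quantize, adc_oversample = as.integer(adc_oversample),
         hold_entry_band_C = hold_entry_band_C,
         stall_timeout_s = stall_timeout_s, sep_band_C = sep_band_C),
    class = "simulation_config"
  )
}

#' Run a full closed-loop protocol simulation
#'
#' Executes a [pcr_protocol()] on the simulated instrument: each tick the
#' sensor reads the block, the stage's scheduled PID computes a signed PWM
#' command, and the plant integrates forward; the heated lid runs
#' concurrently under its hysteresis thermostat. The PID state is reset at
#' every stage transition. A stage's hold timer starts when the measured
#' temperature first enters the hold-entry band, and the stage ends when
#' the hold has elapsed; the timer does not pause if the temperature
#' briefly leaves the band.
#'
#' @param protocol A [pcr_protocol()].
#' @param plant Block [plant_params()]; defaults to the packaged
#'   reference block model.
#' @param lid_plant Lid [plant_params()] (or `NULL` to skip the lid);
#'   defaults to the packaged reference lid model.
#' @param cal,adc Sensor model.
#' @param schedule Gain schedule; stage gains are looked up by kind.
#' @param config A [simulation_config()].
#' @param lid Optional [lid_thermostat()]; defaults to one centred on the
#'   protocol's lid setpoint with a 2 degC band.
#' @return A tibble of class `pcr_trace`, one row per `dt`, with columns
#'   `time_s`, `block_true_C`, `block_measured_C`, `lid_C`, `pwm`,
#'   `direction`, `stage_label`, `cycle_index`, `stage_index`, `kind`,
#'   `target_C`, `phase` (`"ramp"` before hold entry, `"hold"` after).
#' @examples
#' \donttest{
#' tr <- run_protocol(pcr_protocol(cycles = 1))
#' hold_statistics(tr)
#' }
#' @export
run_protocol <- function(protocol = pcr_protocol(),
                         plant = reference_block_params(),
                         lid_plant = reference_lid_params(),
                         cal = sensor_calibration(),
                         adc = adc_config(),
                         schedule = default_gain_schedule(),
                         config = simulation_config(),
                         lid = NULL) {
  stopifnot(inherits(protocol, "pcr_protocol"),
            inherits(plant, "plant_params"),
            inherits(config, "simulation_config"))
  stages <- expand_protocol(protocol)
  lid <- lid %||% lid_thermostat(protocol$lid_setpoint_C, 2)
  withr::local_seed(config$seed)

  Tb <- config$start_temp_C
  has_lid <- !is.null(lid_plant)
  Tl <- if (has_lid) config$lid_start_temp_C %||% lid_plant$ambient_C else NA_real_
  lid_on <- if (has_lid) Tl < lid$setpoint_C else FALSE
  t_off <- 0
  pieces <- vector("list", nrow(stages))

  for (s in seq_len(nrow(stages))) {
    g <- select_gains(schedule, stages$kind[s])
    sim <- sim_stage_internal(
      temp0_C = Tb, target_C = stages$target_C[s], gains = g$gains,
      hold_s = stages$hold_s[s], plant = plant, cal = cal, adc = adc,
      cfg = config, lid_plant = lid_plant, lid0_C = Tl, lid_on0 = lid_on,
      lid_setpoint_C = lid$setpoint_C, lid_band_C = lid$hysteresis_band_C
    )
    if (sim$stalled) {
      abort(sprintf(
        "Stalled protocol: stage '%s' did not reach %g degC (+/- %g) within %g s.",
        stages$stage_label[s], stages$target_C[s],
        config$hold_entry_band_C, config$stall_timeout_s),
        class = "pcrtwin_stall")
    }
    pieces[[s]] <- tibble(
      time_s = t_off + sim$t_local,
      block_true_C = sim$temp_C,
      block_measured_C = sim$measured_C,
      lid_C = sim$lid_C,
      pwm = sim$pwm,
      direction = c("cool", "idle", "heat")[sim$dir + 2L],
      stage_label = stages$stage_label[s],
      cycle_index = stages$cycle_index[s],
      stage_index = stages$stage_index[s],
      kind = stages$kind[s],
      target_C = stages$target_C[s],
      phase = c("ramp", "hold")[sim$phase]
    )
    t_off <- t_off + sim$t_local[length(sim$t_local)]
    Tb <- sim$temp_end_C
    Tl <- sim$lid_end_C
    lid_on <- sim$lid_on
  }

  first <- tibble(
    time_s = 0, block_true_C = config$start_temp_C,
    block_measured_C = NA_real_,
    lid_C = if (has_lid) (config$lid_start_temp_C %||% lid_plant$ambient_C) else NA_real_,
    pwm = 0L, direction = "idle",
    stage_label = stages$stage_label[1], cycle_index = stages$cycle_index[1],
    stage_index = stages$stage_index[1], kind = stages$kind[1],
    target_C = stages$target_C[1], phase = "ramp"
  )
  out <- dplyr::bind_rows(c(list(first), pieces))
  attr(out, "dt") <- config$dt
  attr(out, "seed") <- config$seed
  class(out) <- c("pcr_trace", class(out))
  out
}

#' Coerce a data frame to a protocol trace
#'
#' Validates the column schema shared by [run_protocol()] output,
#' [read_trace()] and the analytic test traces, and restores the
#' `pcr_trace` class.
#'
#' @param x A data frame with at least `time_s`, `block_true_C`,
#'   `stage_label`, `stage_index`, `target_C` and `phase` columns.
#' @return A `pcr_trace` tibble.
#' @export
as_pcr_trace <- function(x) {
  x <- as_tibble(x)
  req <- c("time_s", "block_true_C", "stage_label", "stage_index",
           "target_C", "phase")
  missing <- setdiff(req, names(x))
  if (length(missing)) {
    abort(sprintf("Not a protocol trace; missing columns: %s",
                  paste(missing, collapse = ", ")))
  }
  if (nrow(x) == 0) abort("Empty trace.")
  if (is.unsorted(x$time_s, strictly = TRUE)) {
    abort("`time_s` must be strictly increasing.")
  }
  if (!inherits(x, "pcr_trace")) class(x) <- c("pcr_trace", class(x))
  x
}

# Sampling step of a trace, from attributes or the time axis.
trace_dt <- function(trace) {
  attr(trace, "dt") %||% stats::median(diff(trace$time_s))
}

#' Simulate the heated lid alone under its thermostat
#'
#' Runs the lid plant under the hysteresis thermostat with the same
#' measurement chain and timing as [run_protocol()], without the block.
#' Useful for characterising lid stability.
#'
#' @param lid_plant Lid [plant_params()].
#' @param thermostat A [lid_thermostat()].
#' @param t_end_s Simulated duration, seconds.
#' @param cal,adc Sensor model for the lid sensor.
#' @param config A [simulation_config()]; `dt`, `control_period_s`,
#'   `seed`, `noise_sd_C`, `quantize` and `adc_oversample` are used, and
#'   the lid starts at `lid_start_temp_C` (ambient by default).
#' @return A `pcr_trace`-shaped tibble whose `lid_C` column holds the lid
#'   temperature (the block columns are `NA`), suitable for
#'   [lid_statistics()].
#' @examples
#' \donttest{
#' tr <- simulate_lid(t_end_s = 200)
#' lid_statistics(tr)
#' }
#' @export
simulate_lid <- function(lid_plant = reference_lid_params(),
                         thermostat = lid_thermostat(),
                         t_end_s = 600,
                         cal = sensor_calibration(),
                         adc = adc_config(),
                         config = simulation_config()) {
  stopifnot(inherits(lid_plant, "plant_params"),
            inherits(thermostat, "lid_thermostat"))
  dt <- config$dt
  ce <- as.integer(round(config$control_period_s / dt))
  withr::local_seed(config$seed)
  n <- ceiling(t_end_s / dt)
  b <- cal$b_mV_per_C
  temps <- numeric(n)
  st <- plant_state(config$lid_start_temp_C %||% lid_plant$ambient_C)
  on <- st$temp_C < thermostat$setpoint_C
  for (i in seq_len(n)) {
    if ((i - 1L) %% ce == 0L) {
      meas <- mean(measure_temperature(
        rep(st$temp_C, config$adc_oversample),
        cal, if (isTRUE(config$quantize)) adc else NULL, config$noise_sd_C))
      on <- lid_step(thermostat, meas, on)
    }
    st <- plant_step(st, if (on) 255 else 0, dt, lid_plant)
    temps[i] <- st$temp_C
  }
  as_pcr_trace(tibble(
    time_s = seq_len(n) * dt, block_true_C = NA_real_,
    block_measured_C = NA_real_, lid_C = temps, pwm = NA_integer_,
    direction = NA_character_, stage_label = "001_lid", cycle_index = 0L,
    stage_index = 1L, kind = NA_character_,
    target_C = thermostat$setpoint_C, phase = "hold"
  ))
}
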