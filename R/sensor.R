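#' Linear sensor calibration
#'
#' The temperature sensor obeys a linear law `T = (Vout + a) / b`, where
#' `Vout` is the sensor output in millivolts, `a` is an offset in
#' millivolts and `b` is the sensitivity in millivolts per degree
#' Celsius. The defaults are the reference block-sensor constants
#' obtained by water-bath calibration of the modelled instrument
#' (a = 19.50 mV, b = 10.14 mV/degC); the nominal device sensitivity is
#' 10 mV/degC.
#'
#' @param a_mV Offset in millivolts.
#' @param b_mV_per_C Sensitivity in millivolts per degree Celsius; must be
#'   positive so the voltage-to-temperature map is monotone increasing.
#'
#' @return An object of class `sensor_calibration`.
#' @examples
#' cal <- sensor_calibration()
#' voltage_to_temp(994.5, cal)
#' @export
sensor_calibration <- function(a_mV = 19.50, b_mV_per_C = 10.14) {
  stopifnot_number(a_mV, "a_mV")
  if (!is_number(b_mV_per_C) || b_mV_per_C <= 0) {
    abort("Invalid calibration: sensitivity `b_mV_per_C` must be > 0.")
  }
  structure(list(a_mV = a_mV, b_mV_per_C = b_mV_per_C),
            class = "sensor_calibration")
}

#' @export
print.sensor_calibration <- function(x, ...) {
  cat(sprintf("<sensor_calibration> T = (Vout + %.4g) / %.4g  [mV, degC]\n",
              x$a_mV, x$b_mV_per_C))
  invisible(x)
}

# Operating range of the LM35C variant used on the block and lid.
SENSOR_RANGE_C <- c(-40, 110)

#' Convert sensor voltage to temperature
#'
#' Applies the inverse calibration map `T = (Vout + a) / b`.
#'
#' @param vout_mV Numeric vector of sensor output voltages in millivolts.
#' @param cal A [sensor_calibration()].
#' @return Temperatures in degrees Celsius.
#' @examples
#' voltage_to_temp(994.5, sensor_calibration(19.5, 10.14)) # 100 degC
#' @export
voltage_to_temp <- function(vout_mV, cal = sensor_calibration()) {
  stopifnot(inherits(cal, "sensor_calibration"), is.numeric(vout_mV))
  (vout_mV + cal$a_mV) / cal$b_mV_per_C
}

#' Convert temperature to ideal sensor voltage
#'
#' Forward calibration map `Vout = b * T - a`, the noiseless,
#' unquantized sensor output.
#'
#' @inheritParams voltage_to_temp
#' @param temp_C Temperatures in degrees Celsius.
#' @return Voltages in millivolts.
#' @export
temp_to_voltage <- function(temp_C, cal = sensor_calibration()) {
  stopifnot(inherits(cal, "sensor_calibration"), is.numeric(temp_C))
  cal$b_mV_per_C * temp_C - cal$a_mV
}

#' Simulate one pass through the measurement chain
#'
#' Models the full chain: the sensor converts the true temperature to a
#' voltage, Gaussian voltage noise is added (specified as an equivalent
#' temperature standard deviation, scaled by the sensitivity so noise acts
#' in the voltage domain), the ADC quantizes the result, and the inverse
#' calibration converts back to a temperature reading. Draws from the
#' current R random number generator; seed it (or use the `seed` argument
#' of higher-level functions) for reproducibility.
#'
#' @param true_temp_C Numeric vector of true temperatures in degrees
#'   Celsius. Values outside the sensor's operating range (-40 to 110)
#'   are clamped with a warning.
#' @param cal A [sensor_calibration()].
#' @param adc An [adc_config()], or `NULL` to disable quantization.
#' @param noise_sd_C Gaussian noise standard deviation, in degrees
#'   Celsius equivalent. Zero disables noise.
#' @return Measured temperatures in degrees Celsius.
#' @examples
#' measure_temperature(25, sensor_calibration(0, 10), noise_sd_C = 0)
#' @export
measure_temperature <- function(true_temp_C, cal = sensor_calibration(),
                                adc = adc_config(), noise_sd_C = 0) {
  stopifnot(is.numeric(true_temp_C), inherits(cal, "sensor_calibration"))
  stopifnot_number(noise_sd_C, "noise_sd_C", 0)
  if (any(true_temp_C < SENSOR_RANGE_C[1] | true_temp_C > SENSOR_RANGE_C[2])) {
    warn("True temperature outside the sensor operating range; clamped.")
    true_temp_C <- clamp(true_temp_C, SENSOR_RANGE_C[1], SENSOR_RANGE_C[2])
  }
  v <- temp_to_voltage(true_temp_C, cal)
  if (noise_sd_C > 0) {
    v <- v + rnorm(length(v), 0, noise_sd_C * cal$b_mV_per_C)
  }
  if (!is.null(adc)) v <- adc_quantize(v, adc)
  voltage_to_temp(v, cal)
}

#' Fit a sensor calibration by least squares
#'
#' Ordinary least-squares regression of recorded output voltage on the
#' reference (water-bath) temperature, `Vout = b * T - a`. The fitted
#' slope is the sensitivity `b` and the negated intercept is the offset
#' `a`, so `T = (Vout + a) / b` reproduces the regression line.
#'
#' @param samples A data frame with columns `true_temp_C` and `vout_mV`,
#'   e.g. from [make_calibration_fixture()] or [read_calibration_samples()].
#' @return A `sensor_calibration` that also carries class
#'   `calibration_fit` with the underlying `lm` fit and residual
#'   diagnostics; see [tidy()] and [glance()] methods.
#' @examples
#' s <- make_calibration_fixture(noise_sd_C = 0, quantize = FALSE)
#' fit_calibration(s)
#' @export
fit_calibration <- function(samples) {
  samples <- as_tibble(samples)
  req <- c("true_temp_C", "vout_mV")
  if (!all(req %in% names(samples))) {
    abort("`samples` needs columns `true_temp_C` and `vout_mV`.")
  }
  if (nrow(samples) < 2 || length(unique(samples$true_temp_C)) < 2) {
    abort("Degenerate fit: need >= 2 samples at distinct temperatures.")
  }
  fit <- lm(vout_mV ~ true_temp_C, data = samples)
  b <- unname(coef(fit)[2])
  a <- -unname(coef(fit)[1])
  if (!is.finite(b) || b <= 0) {
    abort("Invalid calibration: fitted sensitivity is not positive.")
  }
  out <- sensor_calibration(a_mV = a, b_mV_per_C = b)
  class(out) <- c("calibration_fit", class(out))
  attr(out, "fit") <- fit
  attr(out, "samples") <- samples
  # residuals in temperature units: reading error along the inverse map
  attr(out, "resid_C") <- unname(stats::residuals(fit)) / b
  out
}

#' @export
print.calibration_fit <- function(x, ...) {
  r <- attr(x, "resid_C")
  cat(sprintf(paste0("<calibration_fit> a = %.4f mV, b = %.4f mV/degC ",
                     "(n = %d, max |resid| = %.3g degC)\n"),
              x$a_mV, x$b_mV_per_C, nrow(attr(x, "samples")),
              max(abs(r))))
  invisible(x)
}

#' @rdname fit_calibration
#' @param x A `calibration_fit`.
#' @param ... Unused.
#' @method tidy calibration_fit
#' @export
tidy.calibration_fit <- function(x, ...) {
  tibble(
    term = c("a_mV", "b_mV_per_C"),
    estimate = c(x$a_mV, x$b_mV_per_C)
  )
}

#' @rdname fit_calibration
#' @method glance calibration_fit
#' @export
glance.calibration_fit <- function(x, ...) {
  fit <- attr(x, "fit")
  r <- attr(x, "resid_C")
  # summary.lm warns on essentially perfect fits; noiseless fits are routine here
  smry <- suppressWarnings(summary(fit))
  tibble(
    n = length(r),
    r.squared = smry$r.squared,
    sigma_mV = smry$sigma,
    max_abs_resid_C = max(abs(r)),
    mean_abs_resid_C = mean(abs(r))
  )
}

#' @rdname fit_calibration
#' @param object A `calibration_fit`.
#' @method autoplot calibration_fit
#' @export
autoplot.calibration_fit <- function(object, ...) {
  samples <- attr(object, "samples")
  ggplot2::ggplot(samples, ggplot2::aes(.data$true_temp_C, .data$vout_mV)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = -object$a_mV, slope = object$b_mV_per_C,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "Reference temperature (°C)", y = "Sensor output (mV)",
      title = sprintf("T = (Vout + %.2f) / %.2f", object$a_mV, object$b_mV_per_C)
    )
}

#' Simulated measurement-error report for a calibrated sensor
#'
#' Simulates repeated measurements on a grid of true temperatures through
#' the full noise + quantization chain and summarises the absolute reading
#' error. This reproduces, in simulation, the water-bath verification of
#' the calibrated sensor.
#'
#' @param cal A [sensor_calibration()].
#' @param adc An [adc_config()], or `NULL` for no quantization.
#' @param noise_sd_C Gaussian noise standard deviation in degrees Celsius.
#' @param grid_C Vector of true temperatures to probe.
#' @param n_per_point Simulated readings per grid temperature.
#' @param seed Integer seed for the simulated noise.
#' @return A one-row tibble with `max_abs_error_C`, `mean_abs_error_C` and
#'   `n`; the per-temperature breakdown is attached as attribute
#'   `"per_point"`.
#' @examples
#' calibration_error_report(noise_sd_C = 0, adc = NULL)$max_abs_error_C
#' @export
calibration_error_report <- function(cal = sensor_calibration(),
                                     adc = adc_config(),
                                     noise_sd_C = 0.08,
                                     grid_C = seq(30, 100, by = 5),
                                     n_per_point = 20,
                                     seed = 1L) {
  if (length(grid_C) == 0) abort("`grid_C` must not be empty.")
  stopifnot_number(n_per_point, "n_per_point", 1)
  withr::local_seed(seed)
  per_point <- purrr::map_dfr(grid_C, function(tt) {
    meas <- measure_temperature(rep(tt, n_per_point), cal, adc, noise_sd_C)
    err <- abs(meas - tt)
    tibble(true_temp_C = tt,
           max_abs_error_C = max(err),
           mean_abs_error_C = mean(err))
  })
  out <- tibble(
    max_abs_error_C = max(per_point$max_abs_error_C),
    mean_abs_error_C = mean(per_point$mean_abs_error_C),
    n = length(grid_C) * n_per_point
  )
  attr(out, "per_point") <- per_point
  out
}
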