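test_that("voltage-to-temperature map matches the calibration line", {
  cal <- sensor_calibration(19.50, 10.14)
  expect_equal(voltage_to_temp(-19.50, cal), 0)
  expect_equal(voltage_to_temp(994.5, cal), 100)
  expect_equal(voltage_to_temp(541.2, cal), 55.296, tolerance = 1e-4)
  expect_equal(temp_to_voltage(100, cal), 994.5)
})

test_that("voltage_to_temp is strictly increasing and inverts the forward map", {
  cal <- sensor_calibration(19.50, 10.14)
  v <- seq(-100, 1100, by = 7)
  expect_true(all(diff(voltage_to_temp(v, cal)) > 0))
  temps <- seq(-40, 110, by = 0.37)
  expect_equal(voltage_to_temp(temp_to_voltage(temps, cal), cal), temps)
})

test_that("invalid calibrations are rejected", {
  expect_error(sensor_calibration(b_mV_per_C = 0), "must be > 0")
  expect_error(sensor_calibration(b_mV_per_C = -2), "must be > 0")
})

test_that("measurement chain is exact without noise and quantization", {
  cal <- sensor_calibration(19.50, 10.14)
  temps <- seq(0, 110, by = 3.3)
  expect_equal(measure_temperature(temps, cal, adc = NULL, noise_sd_C = 0),
               temps)
})

test_that("noiseless quantized measurements err by at most half an LSB", {
  cal <- sensor_calibration(19.50, 10.14)
  adc <- adc_config()
  bound <- adc_lsb_voltage(adc) / (2 * cal$b_mV_per_C)
  temps <- seq(5, 110, by = 0.613)
  err <- abs(measure_temperature(temps, cal, adc, noise_sd_C = 0) - temps)
  expect_true(all(err <= bound + 1e-12))
})

test_that("out-of-range true temperatures are clamped with a warning", {
  expect_warning(measure_temperature(140, adc = NULL), "operating range")
})

test_that("least-squares calibration recovers exact lines", {
  two <- tibble::tibble(true_temp_C = c(0, 10), vout_mV = c(0, 100))
  fit <- fit_calibration(two)
  expect_equal(fit$a_mV, 0)
  expect_equal(fit$b_mV_per_C, 10)

  s <- make_calibration_fixture(a_mV = 19.50, b_mV_per_C = 10.14,
                                noise_sd_C = 0, quantize = FALSE)
  fit <- fit_calibration(s)
  expect_equal(fit$a_mV, 19.50, tolerance = 1e-9)
  expect_equal(fit$b_mV_per_C, 10.14, tolerance = 1e-9)
  expect_equal(tidy(fit)$estimate, c(19.50, 10.14), tolerance = 1e-9)
  expect_gt(glance(fit)$r.squared, 0.999999)
})

test_that("calibration agrees with a brute-force normal-equations solve", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      n <- sample(3:12, 1)
      tt <- runif(n, 20, 100)
      v <- runif(1, 5, 15) * tt - runif(1, -30, 30) + rnorm(n, 0, 2)
      X <- cbind(1, tt)
      beta <- solve(t(X) %*% X, t(X) %*% v) # normal equations, by hand
      fit <- fit_calibration(tibble::tibble(true_temp_C = tt, vout_mV = v))
      expect_equal(fit$b_mV_per_C, beta[2], tolerance = 1e-9,
                   ignore_attr = TRUE)
      expect_equal(fit$a_mV, -beta[1], tolerance = 1e-9, ignore_attr = TRUE)
    }
  })
})

test_that("calibration from noisy samples recovers the truth closely", {
  s <- make_calibration_fixture(a_mV = 19.50, b_mV_per_C = 10.14,
                                grid_C = seq(30, 100, by = 5),
                                noise_sd_C = 0.1, n_per_point = 10,
                                seed = 3, quantize = FALSE)
  fit <- fit_calibration(s)
  expect_equal(fit$b_mV_per_C, 10.14, tolerance = 0.05 / 10.14)
  expect_lt(abs(fit$a_mV - 19.50), 2) # offset is noisier than the slope
  # reading error of the fitted line stays small across the range
  pred <- voltage_to_temp(temp_to_voltage(seq(30, 100, 5),
                                          sensor_calibration(19.5, 10.14)),
                          fit)
  expect_lt(max(abs(pred - seq(30, 100, 5))), 0.05)
})

test_that("degenerate calibration inputs error", {
  expect_error(fit_calibration(tibble::tibble(true_temp_C = 50,
                                              vout_mV = 480)),
               "Degenerate")
  expect_error(fit_calibration(tibble::tibble(true_temp_C = c(50, 50),
                                              vout_mV = c(480, 481))),
               "Degenerate")
  expect_error(fit_calibration(tibble::tibble(x = 1:3, y = 1:3)), "columns")
})

test_that("error report is zero for an ideal chain and bounded under quantization", {
  ideal <- calibration_error_report(noise_sd_C = 0, adc = NULL)
  expect_equal(ideal$max_abs_error_C, 0)

  cal <- sensor_calibration()
  quant_only <- calibration_error_report(cal, adc_config(), noise_sd_C = 0)
  bound <- adc_lsb_voltage(adc_config()) / (2 * cal$b_mV_per_C)
  expect_lte(quant_only$max_abs_error_C, bound + 1e-12)

  expect_error(calibration_error_report(grid_C = numeric(0)), "empty")
})
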