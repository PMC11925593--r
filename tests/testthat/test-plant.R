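test_that("equilibrium temperature follows the closed form", {
  p <- plant_params(2.8, 2.8, 0.02, ambient_C = 25)
  expect_equal(equilibrium_temp(0, p), 25)
  expect_equal(equilibrium_temp(255, p), 165) # 25 + 2.8 / 0.02
  expect_equal(equilibrium_temp(-255, p), -115) # mirrored below ambient
  expect_error(equilibrium_temp(255, plant_params(2.8, 2.8, 0)),
               "No equilibrium")
})

test_that("plant_step is an explicit Euler update with asymmetric gains", {
  p <- plant_params(2.8, 2.0, 0.02, ambient_C = 25)
  # equilibrium is a fixed point
  st <- plant_step(plant_state(25), 0, 0.1, p)
  expect_equal(st$temp_C, 25)
  expect_equal(st$time_s, 0.1)
  # unpowered above ambient: strictly decreasing toward ambient
  st <- plant_state(80)
  for (i in 1:20) {
    st2 <- plant_step(st, 0, 0.5, p)
    expect_lt(st2$temp_C, st$temp_C)
    expect_gt(st2$temp_C, 25)
    st <- st2
  }
  # direction selects the gain
  up <- plant_step(plant_state(50), 255, 1, p)$temp_C - 50
  dn <- 50 - plant_step(plant_state(50), -255, 1, p)$temp_C
  expect_equal(up, 2.8 - 0.02 * 25)
  expect_equal(dn, 2.0 + 0.02 * 25)
  expect_error(plant_step(plant_state(50), 255, 0, p), "positive")
  expect_error(plant_step(plant_state(50), 300, 0.1, p), "<= 255")
})

test_that("trajectories stay bounded by the full-drive equilibria", {
  p <- plant_params(3, 2.5, 0.01, ambient_C = 25)
  lo <- equilibrium_temp(-255, p)
  hi <- equilibrium_temp(255, p)
  withr::with_seed(21, {
    st <- plant_state(60)
    for (u in sample(-255:255, 400, replace = TRUE)) {
      st <- plant_step(st, u, 0.5, p)
      expect_gte(st$temp_C, lo)
      expect_lte(st$temp_C, hi)
    }
  })
})

test_that("equilibrium temperature is non-decreasing in the drive", {
  p <- plant_params(2.8, 3.9, 0.004)
  eq <- equilibrium_temp(seq(-255, 255, by = 5), p)
  expect_true(all(diff(eq) >= 0))
})

test_that("halving the Euler step changes a 120 s trajectory negligibly", {
  p <- plant_params(2.8, 2.0, 0.02)
  coarse <- simulate_plant(p, u = 200, dt = 0.1, t_end_s = 120, temp0_C = 25)
  fine <- simulate_plant(p, u = 200, dt = 0.05, t_end_s = 120, temp0_C = 25)
  shared <- dplyr::inner_join(coarse, fine, by = "time_s")
  expect_lt(max(abs(shared$temp_C.x - shared$temp_C.y)), 0.05)
  expect_lt(0.1 * p$loss_coeff_per_s, 0.1) # documented stability margin
})

test_that("plant calibration recovers synthetic ground-truth parameters", {
  truth <- plant_params(2.5, 3.2, 0.002)
  sched <- default_gain_schedule()
  cal <- sensor_calibration()
  adc <- adc_config()
  cfg <- simulation_config(noise_sd_C = 0)
  targets <- reference_ramp_targets()
  for (r in 1:2) {
    obs <- pcrtwin:::ramp_observables(truth, targets[r, ], sched, cal, adc, cfg)
    targets$duration_s[r] <- obs[["duration"]]
    targets$max_rate_C_per_s[r] <- obs[["max_rate"]]
  }
  fit <- fit_plant_to_observables(targets)
  expect_equal(fit$gain_heat_C_per_s, truth$gain_heat_C_per_s, tolerance = 0.02)
  expect_equal(fit$gain_cool_C_per_s, truth$gain_cool_C_per_s, tolerance = 0.02)
  expect_equal(fit$loss_coeff_per_s, truth$loss_coeff_per_s, tolerance = 0.15)
  expect_lt(max(abs(tidy(fit)$residual[c(1, 3)])), 0.5) # durations, seconds
})

test_that("heating-only targets leave the cooling gain flagged", {
  targets <- reference_ramp_targets()[1, ]
  expect_warning(fit <- fit_plant_to_observables(targets), "unconstrained")
  expect_true(attr(fit, "gain_cool_unconstrained"))
  expect_equal(fit$gain_cool_C_per_s, fit$gain_heat_C_per_s)
  expect_true(glance(fit)$gain_cool_unconstrained)
})

test_that("an unreachable calibration target fails with a diagnostic", {
  bad <- reference_ramp_targets()
  bad$duration_s[1] <- 2 # 68.6 degC in 2 s is outside the search bracket
  expect_error(fit_plant_to_observables(bad), "failed to bracket")
})
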