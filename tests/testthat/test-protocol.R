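test_that("protocol expansion has length 2 + 3 * cycles and preserves order", {
  expect_equal(nrow(expand_protocol(pcr_protocol(cycles = 0))), 2)
  ex <- expand_protocol(pcr_protocol(cycles = 30))
  expect_equal(nrow(ex), 92)
  expect_false(any(duplicated(ex$stage_label)))
  expect_equal(ex$kind[1], "initial_denaturation")
  expect_equal(ex$kind[92], "final_extension")
  body <- matrix(ex$kind[2:91], nrow = 3)
  expect_true(all(body[1, ] == "denaturation"))
  expect_true(all(body[2, ] == "annealing"))
  expect_true(all(body[3, ] == "extension"))
  expect_equal(ex$cycle_index[1], 0L)
  expect_equal(ex$cycle_index[92], 31L)
  expect_equal(unique(ex$cycle_index[2:4]), 1L)
})

test_that("lid thermostat switches with hysteresis", {
  th <- lid_thermostat(105, 2)
  expect_true(lid_step(th, 20, FALSE))
  expect_false(lid_step(th, 107, TRUE))
  expect_true(lid_step(th, 105, TRUE))   # inside the band: keep state
  expect_false(lid_step(th, 105, FALSE))
})

test_that("simulation_config validates its timing", {
  expect_error(simulation_config(dt = 0))
  expect_error(simulation_config(control_period_s = 0.25), "multiple")
  expect_silent(simulation_config(control_period_s = 0.3))
})

test_that("a protocol already at temperature holds for exactly its dwell time", {
  prot <- pcr_protocol(
    initial_denaturation = protocol_stage("initial_denaturation", 26.39, 10),
    cycles = 0L,
    final_extension = protocol_stage("final_extension", 26.39, 10)
  )
  tr <- run_protocol(prot, config = simulation_config(noise_sd_C = 0))
  expect_lte(max(tr$time_s), 20 + 0.5)
  # hold entry is immediate, so virtually the whole trace is hold phase
  expect_true(all(tr$phase[-1] == "hold"))
  for (s in unique(tr$stage_index)) {
    hold <- tr[tr$stage_index == s & tr$phase == "hold", ]
    expect_equal(max(hold$time_s) - min(hold$time_s), 10,
                 tolerance = 0.3 / 10)
  }
})

test_that("hold durations honour the configured dwell from band entry", {
  tr <- small_trace()
  ex <- expand_protocol(pcr_protocol(
    initial_denaturation = protocol_stage("initial_denaturation", 95, 20),
    cycles = 1L,
    final_extension = protocol_stage("final_extension", 72, 20)
  ))
  for (s in ex$stage_index) {
    hold <- tr[tr$stage_index == s & tr$phase == "hold", ]
    dur <- max(hold$time_s) - min(hold$time_s)
    # entry is detected on the controller grid; one control period slack
    expect_lt(abs(dur - ex$hold_s[s]), 0.4)
  }
})

test_that("trace stage accounting matches the expanded protocol", {
  tr <- small_trace()
  expect_equal(length(unique(tr$stage_label)), 5) # 2 + 3 * 1
  expect_equal(sort(unique(tr$stage_index)), 1:5)
  # within every stage the ramp samples precede the hold samples
  by_stage <- split(tr$phase, tr$stage_index)
  for (ph in by_stage) {
    expect_true(all(diff(match(ph, c("ramp", "hold"))) >= 0))
  }
})

test_that("consecutive samples never jump faster than the plant allows", {
  tr <- small_trace()
  p <- reference_block_params()
  dt <- attr(tr, "dt")
  max_step <- max(p$gain_heat_C_per_s, p$gain_cool_C_per_s) * dt * 1.5
  expect_lt(max(abs(diff(tr$block_true_C))), max_step)
})

test_that("the closed loop stays within physical bounds", {
  tr <- small_trace()
  expect_lt(max(tr$block_true_C), 115)
  expect_gt(min(tr$block_true_C), 20)
})

test_that("identical seeds give bit-identical traces", {
  cfg <- simulation_config(seed = 77)
  prot <- pcr_protocol(cycles = 1L,
                       initial_denaturation = protocol_stage("initial_denaturation", 95, 10),
                       final_extension = protocol_stage("final_extension", 72, 10))
  t1 <- run_protocol(prot, config = cfg)
  t2 <- run_protocol(prot, config = cfg)
  expect_identical(t1, t2)
  t3 <- run_protocol(prot, config = simulation_config(seed = 78))
  expect_false(identical(t1$block_measured_C, t3$block_measured_C))
})

test_that("the engine's PID arithmetic is in lock-step with pid_step()", {
  prot <- pcr_protocol(
    initial_denaturation = protocol_stage("initial_denaturation", 95, 15),
    cycles = 0L,
    final_extension = protocol_stage("final_extension", 72, 15)
  )
  cfg <- simulation_config(noise_sd_C = 0)
  tr <- run_protocol(prot, config = cfg, lid_plant = NULL)
  ce <- as.integer(round(cfg$control_period_s / cfg$dt))
  for (s in unique(tr$stage_index)) {
    rows <- tr[tr$stage_index == s & tr$time_s > 0, ]
    g <- select_gains(default_gain_schedule(), rows$kind[1])
    upd <- seq(1, nrow(rows), by = ce) # rows produced under each update
    st <- pid_state()
    for (j in upd) {
      out <- pid_step(g$gains, st, rows$target_C[j], rows$block_measured_C[j],
                      sep_band = cfg$sep_band_C)
      st <- out$state
      expect_equal(rows$pwm[j], out$command$magnitude)
      expect_equal(rows$direction[j], out$command$direction)
    }
  }
})

test_that("an unreachable stage raises a stalled-protocol error naming it", {
  weak <- plant_params(0.05, 0.05, 0.01) # equilibrium far below 95 degC
  prot <- pcr_protocol(cycles = 0L)
  expect_error(
    run_protocol(prot, plant = weak,
                 config = simulation_config(stall_timeout_s = 30)),
    "001_initial_denaturation", class = "pcrtwin_stall"
  )
})
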