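test_that("zero error from a fresh controller gives an idle command", {
  out <- pid_step(pid_gains(15, 1, 7), pid_state(), 95, 95)
  expect_equal(out$command$magnitude, 0L)
  expect_equal(out$command$direction, "idle")
})

test_that("one step of the discrete law matches hand evaluation", {
  # annealing gains, fresh state, 2 degC below target:
  # E = 2, I = 2, D = 2 -> U = 9*2 + 0.1*2 + 5*2 = 28.2 -> 28 counts, heat
  out <- pid_step(pid_gains(9, 0.1, 5), pid_state(), 55, 53)
  expect_equal(out$command$magnitude, 28L)
  expect_equal(out$command$direction, "heat")
  expect_equal(out$state$integral, 2)
  expect_equal(out$state$prev_error, 2)
})

test_that("large errors saturate at the 8-bit PWM limit", {
  out <- pid_step(pid_gains(15, 1, 7), pid_state(), 95, -5)
  expect_equal(out$command$magnitude, 255L)
  expect_equal(out$command$direction, "heat")
  out <- pid_step(pid_gains(15, 1, 7), pid_state(), 25, 125)
  expect_equal(out$command$magnitude, 255L)
  expect_equal(out$command$direction, "cool")
})

test_that("reset clears the state and is idempotent", {
  st <- pid_step(pid_gains(9, 0.1, 5), pid_state(), 55, 53)$state
  expect_true(st$initialized)
  r1 <- pid_reset(st)
  expect_identical(r1, pid_state())
  expect_identical(pid_reset(r1), pid_state())
  # first step after a reset treats the previous error as zero: D = E
  kd_only <- pid_step(pid_gains(0, 0, 4), pid_state(), 60, 58)
  expect_equal(kd_only$command$magnitude, 8L) # Kd * E = 4 * 2
})

test_that("with Ki = Kd = 0 the controller equals the pure-P closed form", {
  withr::with_seed(5, {
    kp <- 12
    gains <- pid_gains(kp, 0, 0)
    st <- pid_state()
    for (meas in runif(300, -50, 150)) {
      out <- pid_step(gains, st, 72, meas)
      st <- out$state
      e <- 72 - meas
      expect_equal(out$command$magnitude,
                   as.integer(min(255, round(abs(kp * e)))))
      expected_dir <- if (out$command$magnitude == 0) "idle"
                      else if (e > 0) "heat" else "cool"
      expect_equal(out$command$direction, expected_dir)
    }
  })
})

test_that("magnitude stays in [0, 255] and the sign is correct on fresh states", {
  withr::with_seed(9, {
    for (rep in 1:5) {
      gains <- pid_gains(runif(1, 0, 30), runif(1, 0, 3), runif(1, 0, 15))
      st <- pid_state()
      for (meas in runif(200, -60, 160)) {
        out <- pid_step(gains, st, 95, meas)
        st <- out$state
        expect_gte(out$command$magnitude, 0L)
        expect_lte(out$command$magnitude, 255L)
        expect_identical(out$command$direction == "idle",
                         out$command$magnitude == 0L)
      }
      # fresh state: direction follows the error sign
      fresh <- pid_step(gains, pid_state(), 95, 70)
      expect_true(fresh$command$direction %in% c("heat", "idle"))
      fresh <- pid_step(gains, pid_state(), 95, 120)
      expect_true(fresh$command$direction %in% c("cool", "idle"))
    }
  })
})

test_that("identical input sequences give identical command sequences", {
  meas <- withr::with_seed(2, 95 - cumprod(rep(0.9, 50)) * 70)
  run_once <- function() {
    st <- pid_state()
    vapply(meas, function(m) {
      out <- pid_step(pid_gains(15, 1, 7), st, 95, m)
      st <<- out$state
      out$command$magnitude
    }, integer(1))
  }
  expect_identical(run_once(), run_once())
})

test_that("the default gain schedule carries the five stage controllers", {
  sched <- default_gain_schedule()
  expect_equal(sched$pid_id, paste0("PID", 1:5))

  ann <- select_gains(sched, "annealing")
  expect_equal(ann$pid_id, "PID3")
  expect_equal(ann$target_C, 55)
  expect_equal(unclass(ann$gains), list(kp = 9, ki = 0.1, kd = 5))

  den <- select_gains(sched, "denaturation")
  expect_equal(den$pid_id, "PID2")
  expect_equal(den$target_C, 95)
  expect_equal(unclass(den$gains), list(kp = 15, ki = 1, kd = 7))

  ext <- select_gains(sched, "extension")
  expect_equal(unclass(ext$gains), list(kp = 13, ki = 1, kd = 10))
  expect_equal(ext$target_C, 72)

  expect_error(select_gains(sched, "elongation"), "Unknown stage kind")
})

test_that("gain-schedule overrides replace only the named fields", {
  sched <- default_gain_schedule(list(annealing = list(kp = 100, kd = 0)))
  ann <- select_gains(sched, "annealing")
  expect_equal(ann$gains$kp, 100)
  expect_equal(ann$gains$kd, 0)
  expect_equal(ann$gains$ki, 0.1)
  expect_error(default_gain_schedule(list(cooling = list(kp = 1))),
               "Unknown stage kind")
})

test_that("negative gains are rejected", {
  expect_error(pid_gains(-1, 0, 0))
})
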