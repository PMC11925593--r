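# Closed-loop simulation engine.
#
# The inner loop is deliberately written in plain scalar R (no S3 dispatch
# per tick): a full 30-cycle protocol is ~50k plant ticks and ~25k
# controller updates. The PID arithmetic here must stay in lock-step with
# pid_step(); a regression test replays a trace through pid_step() to
# guarantee that.

# Windowed slope estimator shared by the metrics and the plant fit: the
# maximum absolute slope of a centred moving window (default 1 s wide).
# Per-tick differences would be dominated by sensor quantization steps.
moving_max_rate <- function(temps, dt, window_s = 1) {
  n <- length(temps)
  if (n < 2) return(NA_real_)
  h <- max(1L, round(window_s / dt / 2))
  if (n < 2 * h + 1) return(abs(temps[n] - temps[1]) / ((n - 1) * dt))
  i <- (h + 1):(n - h)
  max(abs(temps[i + h] - temps[i - h]) / (2 * h * dt))
}

# Simulate a single protocol stage. Temperatures evolve at cfg$dt; the
# controller (and lid thermostat) update every cfg$control_period_s with a
# zero-order hold on the PWM command in between, mirroring a firmware loop
# that is slower than the physics.
#
# Returns stage-local vectors; the caller stitches stages together.
sim_stage_internal <- function(temp0_C, target_C, gains, hold_s,
                               plant, cal, adc, cfg,
                               lid_plant = NULL, lid0_C = NULL,
                               lid_on0 = TRUE, lid_setpoint_C = 105,
                               lid_band_C = 2,
                               stop_on_cross = FALSE, t_max_s = NULL) {
  dt <- cfg$dt
  ce <- as.integer(round(cfg$control_period_s / dt))
  a <- cal$a_mV
  b <- cal$b_mV_per_C
  quant <- isTRUE(cfg$quantize) && !is.null(adc)
  lsb <- if (quant) adc_lsb_voltage(adc) else NA_real_
  vref <- if (quant) adc$reference_voltage_mV else NA_real_
  sd_mV <- cfg$noise_sd_C * b
  m_over <- as.integer(cfg$adc_oversample %||% 1L)
  kp <- gains$kp; ki <- gains$ki; kd <- gains$kd
  sep <- cfg$sep_band_C
  imax <- 255 / max(ki, .Machine$double.eps)
  gh <- plant$gain_heat_C_per_s
  gc <- plant$gain_cool_C_per_s
  kl <- plant$loss_coeff_per_s
  amb <- plant$ambient_C
  has_lid <- !is.null(lid_plant)
  if (has_lid) {
    lgh <- lid_plant$gain_heat_C_per_s
    lkl <- lid_plant$loss_coeff_per_s
    lamb <- lid_plant$ambient_C
  }
  t_max <- t_max_s %||% (cfg$stall_timeout_s + hold_s)
  n_cap <- ceiling(t_max / dt) + 1L

  temp <- numeric(n_cap); lidv <- numeric(n_cap); measv <- numeric(n_cap)
  pwm <- integer(n_cap); dirv <- integer(n_cap); phase <- integer(n_cap)

  Tb <- temp0_C
  Tl <- lid0_C %||% NA_real_
  lid_on <- lid_on0
  I <- 0; prevE <- 0; u <- 0L
  meas <- NA_real_
  entered <- FALSE; t_entry <- NA_real_
  cross_time <- NA_real_
  heating <- target_C > temp0_C
  stalled <- FALSE
  i <- 0L

  while (i < n_cap) {
    if (i %% ce == 0L) {
      v <- b * Tb - a
      if (sd_mV > 0) v <- v + rnorm(m_over, 0, sd_mV)
      if (quant) {
        v <- pmin(pmax(v, 0), vref)
        v <- round(v / lsb) * lsb
      }
      meas <- (mean(v) + a) / b
      e <- target_C - meas
      d <- e - prevE
      i_new <- I
      if (abs(e) <= sep) i_new <- min(max(I + e, -imax), imax)
      uu <- kp * e + ki * i_new + kd * d
      if (abs(uu) > 255) {
        i_new <- I
        uu <- kp * e + ki * i_new + kd * d
      }
      I <- i_new; prevE <- e
      u <- min(255, round(abs(uu))) * sign(uu)
      if (has_lid) {
        lv <- b * Tl - a
        if (sd_mV > 0) lv <- lv + rnorm(m_over, 0, sd_mV)
        if (quant) {
          lv <- pmin(pmax(lv, 0), vref)
          lv <- round(lv / lsb) * lsb
        }
        lmeas <- (mean(lv) + a) / b
        if (lmeas < lid_setpoint_C - lid_band_C / 2) lid_on <- TRUE
        else if (lmeas > lid_setpoint_C + lid_band_C / 2) lid_on <- FALSE
      }
      if (!entered && abs(meas - target_C) <= cfg$hold_entry_band_C) {
        entered <- TRUE
        t_entry <- i * dt
      }
    }
    g <- if (u >= 0) gh else gc
    Tnew <- Tb + dt * (g * u / 255 - kl * (Tb - amb))
    if (has_lid) Tl <- Tl + dt * (lgh * (if (lid_on) 1 else 0) - lkl * (Tl - lamb))
    i <- i + 1L
    if (is.na(cross_time) &&
        (if (heating) Tnew >= target_C else Tnew <= target_C)) {
      cross_time <- i * dt
    }
    Tb <- Tnew
    temp[i] <- Tb; lidv[i] <- Tl; measv[i] <- meas
    pwm[i] <- abs(u); dirv[i] <- sign(u)
    phase[i] <- if (entered) 2L else 1L
    if (stop_on_cross && !is.na(cross_time)) break
    if (entered && i * dt - t_entry >= hold_s) break
    if (!entered && i * dt > cfg$stall_timeout_s) { stalled <- TRUE; break }
  }
  n <- i
  list(
    temp_C = temp[seq_len(n)], lid_C = lidv[seq_len(n)],
    measured_C = measv[seq_len(n)], pwm = pwm[seq_len(n)],
    dir = dirv[seq_len(n)], phase = phase[seq_len(n)],
    t_local = seq_len(n) * dt,
    t_entry = t_entry, cross_time_s = cross_time,
    stalled = stalled, lid_end_C = Tl, lid_on = lid_on, temp_end_C = Tb
  )
}

# Single-stage closed-loop ramp used by the plant calibration.
closed_loop_stage <- function(start_C, target_C, gains, params, cal, adc,
                              cfg, stop_on_cross = TRUE, t_max_s = 400) {
  sim <- sim_stage_internal(
    temp0_C = start_C, target_C = target_C, gains = gains, hold_s = Inf,
    plant = params, cal = cal, adc = adc, cfg = cfg,
    stop_on_cross = stop_on_cross, t_max_s = t_max_s
  )
  # include the starting sample so rate windows cover the ramp onset
  sim$temp_C <- c(start_C, sim$temp_C)
  sim
}
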