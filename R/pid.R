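#' PID gain triple
#'
#' @param kp,ki,kd Proportional, integral and derivative coefficients of
#'   the discrete PID law `U(n) = Kp*E(n) + Ki*I(n) + Kd*D(n)`, where
#'   `E` is the setpoint error in degrees Celsius, `I` the running sum of
#'   errors and `D` the difference between consecutive errors. All
#'   coefficients must be non-negative.
#' @return An object of class `pid_gains`.
#' @examples
#' pid_gains(9, 0.1, 5)
#' @export
pid_gains <- function(kp, ki, kd) {
  for (g in list(kp = kp, ki = ki, kd = kd)) stopifnot_number(g, "gain", 0)
  structure(list(kp = kp, ki = ki, kd = kd), class = "pid_gains")
}

#' @export
print.pid_gains <- function(x, ...) {
  cat(sprintf("<pid_gains> Kp = %g, Ki = %g, Kd = %g\n", x$kp, x$ki, x$kd))
  invisible(x)
}

#' Fresh PID controller state
#'
#' @return A `pid_state` with zero integral, zero previous error and the
#'   initialized flag cleared. On the first [pid_step()] after a reset the
#'   previous error is treated as zero, so the derivative contribution is
#'   `Kd * E`.
#' @export
pid_state <- function() {
  structure(list(integral = 0, prev_error = 0, initialized = FALSE),
            class = "pid_state")
}

#' Reset a PID controller state
#'
#' Clears the integral and the stored previous error. Idempotent. The
#' protocol engine applies this at every stage transition, so each PCR
#' stage starts from a fresh controller.
#'
#' @param state A `pid_state` (ignored; present so the reset can be
#'   written in a pipeline).
#' @return A fresh `pid_state`.
#' @export
pid_reset <- function(state = pid_state()) pid_state()

#' One update of the discrete PID law
#'
#' Computes the error `E = target - measured`, accumulates the integral
#' `I`, forms the difference term `D = E - E_prev`, and evaluates
#' `U = Kp*E + Ki*I + Kd*D`. The command magnitude saturates at 255 so it
#' fits an 8-bit PWM duty cycle, and the sign of `U` selects the drive
#' direction (heat for positive, cool for negative, idle at zero).
#'
#' Two anti-windup safeguards shape the integral: accumulation only
#' happens inside a separation band (`|E| <= sep_band`), so the large
#' errors of a ramp never wind the sum up; and accumulation is skipped on
#' any update whose output saturates (conditional integration). The
#' integral is additionally clamped so `Ki * I` cannot exceed the
#' actuator range by itself.
#'
#' @param gains A [pid_gains()].
#' @param state A `pid_state`; use [pid_state()] for a fresh controller.
#' @param target_C,measured_C Setpoint and measured temperature in
#'   degrees Celsius.
#' @param sep_band Integral separation band in degrees Celsius.
#' @return A list with `command` (a `drive_command`: integer `magnitude`
#'   in PWM counts 0-255 and `direction` among `"heat"`, `"cool"`,
#'   `"idle"`) and the updated `state`.
#' @examples
#' st <- pid_step(pid_gains(9, 0.1, 5), pid_state(), 55, 53)
#' st$command
#' @export
pid_step <- function(gains, state, target_C, measured_C, sep_band = 2) {
  stopifnot(inherits(gains, "pid_gains"), inherits(state, "pid_state"),
            is_number(target_C), is_number(measured_C))
  e <- target_C - measured_C
  prev <- if (state$initialized) state$prev_error else 0
  d <- e - prev
  i_limit <- 255 / max(gains$ki, .Machine$double.eps)
  i_new <- state$integral
  if (abs(e) <= sep_band) i_new <- clamp(state$integral + e, -i_limit, i_limit)
  u <- gains$kp * e + gains$ki * i_new + gains$kd * d
  if (abs(u) > 255) { # saturated: keep the previous integral
    i_new <- state$integral
    u <- gains$kp * e + gains$ki * i_new + gains$kd * d
  }
  magnitude <- min(255, round(abs(u)))
  direction <- if (magnitude == 0) "idle" else if (u > 0) "heat" else "cool"
  list(
    command = structure(list(magnitude = as.integer(magnitude),
                             direction = direction),
                        class = "drive_command"),
    state = structure(list(integral = i_new, prev_error = e,
                           initialized = TRUE),
                      class = "pid_state")
  )
}

#' @export
print.drive_command <- function(x, ...) {
  cat(sprintf("<drive_command> %s @ %d/255\n", x$direction, x$magnitude))
  invisible(x)
}

#' The stage-wise PID gain schedule
#'
#' The controller is "piecewise": each PCR stage runs its own PID with its
#' own coefficients. The default schedule maps the five stage kinds to
#' controllers PID1-PID5:
#'
#' | stage | PID | target (degC) | Kp | Ki | Kd |
#' |---|---|---|---|---|---|
#' | initial_denaturation | PID1 | 95 | 15 | 1 | 7 |
#' | denaturation | PID2 | 95 | 15 | 1 | 7 |
#' | annealing | PID3 | 55 | 9 | 0.1 | 5 |
#' | extension | PID4 | 72 | 13 | 1 | 10 |
#' | final_extension | PID5 | 72 | 13 | 1 | 10 |
#'
#' @param overrides Optional named list: for a stage kind, a list with any
#'   of `kp`, `ki`, `kd`, `target_C` replacing the default.
#' @return A tibble of class `gain_schedule` with columns `stage_kind`,
#'   `pid_id`, `target_C`, `kp`, `ki`, `kd`.
#' @examples
#' default_gain_schedule()
#' @export
default_gain_schedule <- function(overrides = NULL) {
  sched <- tibble(
    stage_kind = c("initial_denaturation", "denaturation", "annealing",
                   "extension", "final_extension"),
    pid_id = paste0("PID", 1:5),
    target_C = c(95, 95, 55, 72, 72),
    kp = c(15, 15, 9, 13, 13),
    ki = c(1, 1, 0.1, 1, 1),
    kd = c(7, 7, 5, 10, 10)
  )
  for (kind in names(overrides)) {
    if (!kind %in% sched$stage_kind) {
      abort(sprintf("Unknown stage kind in overrides: '%s'", kind))
    }
    for (f in names(overrides[[kind]])) {
      if (!f %in% c("kp", "ki", "kd", "target_C")) {
        abort(sprintf("Unknown gain-schedule field '%s'", f))
      }
      sched[sched$stage_kind == kind, f] <- overrides[[kind]][[f]]
    }
  }
  class(sched) <- c("gain_schedule", class(sched))
  sched
}

#' Look up the controller for a PCR stage
#'
#' @param schedule A [default_gain_schedule()]-style tibble.
#' @param stage_kind One of `"initial_denaturation"`, `"denaturation"`,
#'   `"annealing"`, `"extension"`, `"final_extension"`.
#' @return A list with `pid_id`, `gains` (a [pid_gains()]) and `target_C`.
#' @examples
#' select_gains(default_gain_schedule(), "annealing")
#' @export
select_gains <- function(schedule = default_gain_schedule(), stage_kind) {
  row <- schedule[schedule$stage_kind == stage_kind, ]
  if (nrow(row) != 1) {
    abort(sprintf("Unknown stage kind '%s'; schedule defines: %s",
                  stage_kind, paste(schedule$stage_kind, collapse = ", ")))
  }
  list(pid_id = row$pid_id,
       gains = pid_gains(row$kp, row$ki, row$kd),
       target_C = row$target_C)
}
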