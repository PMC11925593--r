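#' Detect and characterise ramps in a protocol trace
#'
#' A ramp spans from a stage transition (the last sample of the previous
#' stage, or the first sample of the trace for the opening stage) to the
#' first sample at or beyond the new stage's target. For each ramp the
#' report gives the start temperature at the transition sample, the
#' duration, the average rate `|target - start| / duration`, and the
#' maximum rate estimated with a centred 1 s moving-window slope (window
#' averaging keeps sensor-quantization steps from fabricating rate
#' spikes). Stages whose target is never crossed are flagged
#' `open_ramp = TRUE` with `NA` duration.
#'
#' @param trace A `pcr_trace` (see [run_protocol()], [read_trace()]).
#' @param targets Optional named numeric vector overriding the per-stage
#'   targets stored in the trace (`names` = stage labels).
#' @param window_s Width of the max-rate moving window, seconds.
#' @return A tibble with one row per stage: `stage_index`, `stage_label`,
#'   `kind`, `start_time_s`, `start_temp_C`, `target_C`, `duration_s`,
#'   `avg_rate_C_per_s`, `max_rate_C_per_s`, `direction`, `open_ramp`.
#' @export
detect_ramps <- function(trace, targets = NULL, window_s = 1) {
  trace <- as_pcr_trace(trace)
  dt <- trace_dt(trace)
  idx <- split(seq_len(nrow(trace)), trace$stage_index)
  purrr::map_dfr(idx, function(ii) {
    s0 <- ii[1]
    target <- trace$target_C[s0]
    label <- trace$stage_label[s0]
    if (!is.null(targets) && label %in% names(targets)) {
      target <- targets[[label]]
    }
    # transition sample: last sample of the previous stage (or trace start)
    i_start <- if (s0 > 1) s0 - 1L else s0
    start_temp <- trace$block_true_C[i_start]
    start_time <- trace$time_s[i_start]
    heating <- target >= start_temp
    temps <- trace$block_true_C[ii]
    hit <- if (heating) which(temps >= target) else which(temps <= target)
    open_ramp <- length(hit) == 0
    if (open_ramp) {
      i_cross <- ii[length(ii)]
      duration <- NA_real_
    } else {
      i_cross <- ii[hit[1]]
      duration <- trace$time_s[i_cross] - start_time
    }
    seg <- trace$block_true_C[i_start:i_cross]
    tibble(
      stage_index = trace$stage_index[s0],
      stage_label = label,
      kind = if ("kind" %in% names(trace)) trace$kind[s0] else NA_character_,
      start_time_s = start_time,
      start_temp_C = start_temp,
      target_C = target,
      duration_s = duration,
      avg_rate_C_per_s = if (is.na(duration) || duration <= 0) NA_real_
                         else abs(target - start_temp) / duration,
      max_rate_C_per_s = moving_max_rate(seg, dt, window_s),
      direction = if (heating) "heating" else "cooling",
      open_ramp = open_ramp
    )
  })
}

#' Hold accuracy statistics
#'
#' For every hold segment (the `phase == "hold"` portion of each stage,
#' which begins when the measured temperature first enters the hold-entry
#' band), drops the first `settling_exclusion_s` seconds and reports the
#' maximum absolute error, the mean signed error, and the peak overshoot
#' beyond the target over the whole stage.
#'
#' @param trace A `pcr_trace`.
#' @param settling_exclusion_s Settling time excluded from the error
#'   statistics (default 5 s). Holds shorter than the exclusion are
#'   reported on the full hold with a warning.
#' @return A tibble with one row per hold: `stage_index`, `stage_label`,
#'   `target_C`, `n`, `max_abs_error_C`, `mean_error_C`, `overshoot_C`.
#' @export
hold_statistics <- function(trace, settling_exclusion_s = 5) {
  trace <- as_pcr_trace(trace)
  stopifnot_number(settling_exclusion_s, "settling_exclusion_s", 0)
  idx <- split(seq_len(nrow(trace)), trace$stage_index)
  short <- character(0)
  out <- purrr::map_dfr(idx, function(ii) {
    hold <- ii[trace$phase[ii] == "hold"]
    if (length(hold) == 0) return(NULL)
    s0 <- ii[1]
    target <- trace$target_C[s0]
    t0 <- trace$time_s[hold[1]]
    settled <- hold[trace$time_s[hold] >= t0 + settling_exclusion_s]
    if (length(settled) == 0) {
      short <<- c(short, trace$stage_label[s0])
      settled <- hold
    }
    err <- trace$block_true_C[settled] - target
    # overshoot judged over the whole stage, in the approach direction
    start_temp <- trace$block_true_C[if (s0 > 1) s0 - 1L else s0]
    dir <- if (target >= start_temp) 1 else -1
    over <- max(c(0, dir * (trace$block_true_C[ii] - target)))
    tibble(
      stage_index = trace$stage_index[s0],
      stage_label = trace$stage_label[s0],
      target_C = target,
      n = length(settled),
      max_abs_error_C = max(abs(err)),
      mean_error_C = mean(err),
      overshoot_C = over
    )
  })
  if (length(short)) {
    warn(sprintf("Hold shorter than the settling exclusion in: %s (full hold used).",
                 paste(short, collapse = ", ")))
  }
  out
}

#' Heated-lid stability statistics
#'
#' @param trace A `pcr_trace` with a `lid_C` column.
#' @param setpoint_C Lid setpoint, degC.
#' @return A one-row tibble: `first_crossing_s` (when the lid first
#'   reaches the setpoint) and `max_abs_dev_C`, the maximum absolute
#'   deviation from the setpoint after that crossing.
#' @export
lid_statistics <- function(trace, setpoint_C = 105) {
  trace <- as_pcr_trace(trace)
  if (!"lid_C" %in% names(trace) || all(is.na(trace$lid_C))) {
    abort("Trace has no lid temperature column.")
  }
  cross <- which(trace$lid_C >= setpoint_C)[1]
  if (is.na(cross)) {
    return(tibble(first_crossing_s = NA_real_, max_abs_dev_C = NA_real_))
  }
  tibble(
    first_crossing_s = trace$time_s[cross],
    max_abs_dev_C = max(abs(trace$lid_C[cross:nrow(trace)] - setpoint_C))
  )
}

#' Default pass/fail thresholds for a performance report
#'
#' The instrument's published performance envelope: every hold within
#' 1 degC of target after settling, and the lid within 2 degC of its
#' setpoint once settled.
#'
#' @return A named list of thresholds.
#' @export
default_thresholds <- function() {
  list(hold_max_abs_error_C = 1, lid_max_abs_dev_C = 2)
}

#' Summarise a trace against performance thresholds
#'
#' Combines [detect_ramps()], [hold_statistics()] and [lid_statistics()]
#' into a single report with pass/fail checks, the quality-control gate
#' used by the `analyze` command.
#'
#' @param trace A `pcr_trace`.
#' @param thresholds See [default_thresholds()].
#' @param settling_exclusion_s Passed to [hold_statistics()].
#' @param lid_setpoint_C Lid setpoint; `NULL` skips the lid check.
#' @return A `performance_report` list with elements `ramps`, `holds`,
#'   `lid` and `checks` (tibble of metric, value, threshold, pass).
#'   `tidy()` returns the checks, `glance()` a one-row summary.
#' @export
performance_report <- function(trace, thresholds = default_thresholds(),
                               settling_exclusion_s = 5,
                               lid_setpoint_C = 105) {
  trace <- as_pcr_trace(trace)
  ramps <- detect_ramps(trace)
  holds <- hold_statistics(trace, settling_exclusion_s)
  has_lid <- !is.null(lid_setpoint_C) && "lid_C" %in% names(trace) &&
    !all(is.na(trace$lid_C))
  lid <- if (has_lid) lid_statistics(trace, lid_setpoint_C) else NULL
  checks <- tibble(
    metric = "hold_max_abs_error_C",
    value = if (nrow(holds)) max(holds$max_abs_error_C) else NA_real_,
    threshold = thresholds$hold_max_abs_error_C
  )
  if (has_lid) {
    checks <- dplyr::bind_rows(checks, tibble(
      metric = "lid_max_abs_dev_C",
      value = lid$max_abs_dev_C,
      threshold = thresholds$lid_max_abs_dev_C
    ))
  }
  checks$pass <- !is.na(checks$value) & checks$value <= checks$threshold
  structure(list(ramps = ramps, holds = holds, lid = lid, checks = checks),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat("<performance_report>\n\nRamps:\n")
  print(x$ramps)
  cat("\nHolds:\n")
  print(x$holds)
  if (!is.null(x$lid)) {
    cat("\nLid:\n")
    print(x$lid)
  }
  cat("\nChecks:\n")
  print(x$checks)
  invisible(x)
}

#' @rdname performance_report
#' @param x,object A `performance_report`.
#' @param ... Unused.
#' @method tidy performance_report
#' @export
tidy.performance_report <- function(x, ...) x$checks

#' @rdname performance_report
#' @method glance performance_report
#' @export
glance.performance_report <- function(x, ...) {
  tibble(
    n_stages = nrow(x$ramps),
    n_holds = nrow(x$holds),
    worst_hold_error_C = if (nrow(x$holds)) max(x$holds$max_abs_error_C) else NA_real_,
    lid_max_abs_dev_C = if (!is.null(x$lid)) x$lid$max_abs_dev_C else NA_real_,
    all_pass = all(x$checks$pass)
  )
}
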