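#' Plot a protocol trace
#'
#' Block temperature over time, coloured by stage kind, with the stage
#' targets as thin reference segments and (when present) the lid
#' temperature as a dashed line.
#'
#' @param object A `pcr_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pcr_trace
#' @export
autoplot.pcr_trace <- function(object, ...) {
  object <- as_pcr_trace(object)
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$block_true_C)) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$kind, group = 1)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$target_C), colour = "grey40",
                       linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = "Block temperature (°C)",
                  colour = "Stage")
  if ("lid_C" %in% names(object) && !all(is.na(object$lid_C))) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$lid_C),
                                linetype = "dashed", colour = "grey30")
  }
  p
}

#' Plot hold errors per stage
#'
#' Settled maximum absolute hold error for every stage of a trace, with
#' the tolerance drawn as a horizontal line.
#'
#' @param trace A `pcr_trace`.
#' @param tolerance_C Hold tolerance, degC.
#' @param settling_exclusion_s Passed to [hold_statistics()].
#' @return A ggplot object.
#' @export
plot_hold_errors <- function(trace, tolerance_C = 1, settling_exclusion_s = 5) {
  holds <- hold_statistics(trace, settling_exclusion_s)
  ggplot2::ggplot(holds,
                  ggplot2::aes(.data$stage_index, .data$max_abs_error_C)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$target_C))) +
    ggplot2::geom_hline(yintercept = tolerance_C, linetype = "dashed") +
    ggplot2::labs(x = "Stage", y = "Settled max |error| (°C)",
                  colour = "Target (°C)")
}

#' @importFrom ggplot2 .data
NULL
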