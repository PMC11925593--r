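#' Analog-to-digital converter configuration
#'
#' Describes the ADC that digitizes the temperature sensor's output
#' voltage. The defaults correspond to a 10-bit converter referenced to
#' 5 V, for which one count spans 5000 mV / 2^10 = 4.8828 mV.
#'
#' @param reference_voltage_mV Full-scale reference voltage in millivolts.
#' @param bits Converter resolution in bits.
#'
#' @return An object of class `adc_config`.
#' @examples
#' adc <- adc_config()
#' adc_lsb_voltage(adc)
#' @export
adc_config <- function(reference_voltage_mV = 5000, bits = 10L) {
  stopifnot_number(reference_voltage_mV, "reference_voltage_mV", 0, strict = TRUE)
  stopifnot_number(bits, "bits", 1)
  if (bits != as.integer(bits)) abort("`bits` must be a whole number.")
  structure(
    list(reference_voltage_mV = reference_voltage_mV, bits = as.integer(bits)),
    class = "adc_config"
  )
}

#' @export
print.adc_config <- function(x, ...) {
  cat(sprintf("<adc_config> %g mV full scale, %d bits (LSB = %.4f mV)\n",
              x$reference_voltage_mV, x$bits, adc_lsb_voltage(x)))
  invisible(x)
}

#' Voltage spanned by one ADC count
#'
#' @param adc An [adc_config()].
#' @return The least-significant-bit voltage in millivolts,
#'   `reference_voltage_mV / 2^bits`.
#' @examples
#' adc_lsb_voltage(adc_config(5000, 10)) # 4.8828 mV
#' @export
adc_lsb_voltage <- function(adc = adc_config()) {
  stopifnot(inherits(adc, "adc_config"))
  adc$reference_voltage_mV / 2^adc$bits
}

#' Quantize a voltage to the ADC grid
#'
#' Rounds a voltage to the nearest ADC count, so the quantization error is
#' at most half an LSB. Voltages outside `[0, reference]` are clamped with
#' a warning, mirroring how a real converter rails.
#'
#' @param voltage_mV Numeric vector of voltages in millivolts.
#' @param adc An [adc_config()].
#' @return Quantized voltages in millivolts.
#' @examples
#' adc_quantize(7, adc_config()) # one count = 4.8828 mV
#' @export
adc_quantize <- function(voltage_mV, adc = adc_config()) {
  stopifnot(inherits(adc, "adc_config"), is.numeric(voltage_mV))
  hi <- adc$reference_voltage_mV
  if (any(voltage_mV < 0 | voltage_mV > hi, na.rm = TRUE)) {
    warn("Voltage outside the ADC range was clamped to [0, reference].")
    voltage_mV <- clamp(voltage_mV, 0, hi)
  }
  lsb <- adc_lsb_voltage(adc)
  round(voltage_mV / lsb) * lsb
}
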