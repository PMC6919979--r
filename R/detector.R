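#' Detector configuration
#'
#' Fixed instrument constants of the reader: the voltage-divider reference
#' resistor, the ADC full scale, the acquisition protocol (LED warm-up, number
#' of reads per data point, read spacing) and the one-digit ADC uncertainty
#' used in the systematic error budget.
#'
#' The LDR sits in a voltage divider against `r_ref`; the microcontroller
#' reads the divider voltage as an integer number of ADC counts between 0 and
#' `u0_counts` (the supply voltage). One data point of the device is the
#' aggregate of `n_reads` consecutive reads spaced `read_interval_ms` apart,
#' taken after `warmup_s` seconds of LED-on equilibration.
#'
#' @param r_ref Reference resistance of the voltage divider, kOhm. The default
#'   750 kOhm is half the LDR's dark resistance, maximising dynamic range.
#' @param adc_bits ADC resolution in bits; full scale is `2^adc_bits - 1`.
#' @param dark_resistance LDR resistance in darkness, kOhm.
#' @param warmup_s LED warm-up / LDR equilibration time before reads, seconds.
#' @param n_reads Number of ADC reads aggregated into one data point.
#' @param read_interval_ms Spacing between consecutive reads, milliseconds.
#' @param delta_u_counts One-digit ADC uncertainty (standard deviation, in
#'   counts) applied to both the divider reading and the supply reading in the
#'   systematic error budget.
#' @return An object of class `ldr_detector_config` (a named list with the
#'   above fields plus `u0_counts`).
#' @examples
#' cfg <- detector_config()
#' cfg$u0_counts  # 1023 for a 10-bit ADC
#' @export
detector_config <- function(r_ref = 750, adc_bits = 10, dark_resistance = 1600,
                            warmup_s = 30, n_reads = 50, read_interval_ms = 50,
                            delta_u_counts = 1) {
  stopifnot(r_ref > 0, adc_bits >= 1, dark_resistance > 0,
            warmup_s >= 0, n_reads >= 1, read_interval_ms > 0,
            delta_u_counts >= 0)
  structure(list(
    r_ref = r_ref,
    adc_bits = as.integer(adc_bits),
    u0_counts = 2L^as.integer(adc_bits) - 1L,
    dark_resistance = dark_resistance,
    warmup_s = warmup_s,
    n_reads = as.integer(n_reads),
    read_interval_ms = read_interval_ms,
    delta_u_counts = delta_u_counts
  ), class = "ldr_detector_config")
}

#' @export
print.ldr_detector_config <- function(x, ...) {
  cat("LDR detector configuration\n")
  cat(sprintf("  reference resistance : %g kOhm\n", x$r_ref))
  cat(sprintf("  ADC                  : %d bit (full scale %d counts, +/- %g digit)\n",
              x$adc_bits, x$u0_counts, x$delta_u_counts))
  cat(sprintf("  acquisition          : %d reads x %g ms after %g s warm-up\n",
              x$n_reads, x$read_interval_ms, x$warmup_s))
  invisible(x)
}

#' Convert ADC counts to LDR resistance
#'
#' Inverts the voltage divider: `R = r_ref * (u0 / u - 1)`, where `u` is the
#' measured divider voltage in ADC counts and `u0` the supply full scale.
#' Strictly decreasing in `u`; full-scale light (`u = u0`) maps to 0 kOhm.
#'
#' @param u_ldr Numeric vector of ADC counts in `(0, u0_counts]`. Real values
#'   are accepted: quantization is a property of the simulator, not of the
#'   conversion.
#' @param cfg A [detector_config()].
#' @return Resistance in kOhm, same length as `u_ldr`.
#' @examples
#' counts_to_resistance(341, detector_config())  # 1500 kOhm
#' @export
counts_to_resistance <- function(u_ldr, cfg = detector_config()) {
  if (length(u_ldr) == 0L) stop("no counts supplied")
  if (any(!is.finite(u_ldr))) stop("non-finite ADC counts")
  if (any(u_ldr <= 0)) {
    stop("ADC count <= 0: divider in darkness/saturation, resistance undefined")
  }
  if (any(u_ldr > cfg$u0_counts)) {
    stop(sprintf("ADC count above full scale (%d)", cfg$u0_counts))
  }
  cfg$r_ref * (cfg$u0_counts / u_ldr - 1)
}

#' Convert resistance to ideal (real-valued) ADC counts
#'
#' Exact inverse of [counts_to_resistance()]: `u = u0 * r_ref / (r_ref + R)`.
#' Returns real-valued counts; integer quantization is applied separately by
#' the simulator.
#'
#' @param r Resistance in kOhm, `>= 0`.
#' @param cfg A [detector_config()].
#' @return Real-valued ADC counts.
#' @examples
#' resistance_to_counts(750)  # 511.5: divider at midpoint
#' @export
resistance_to_counts <- function(r, cfg = detector_config()) {
  if (any(!is.finite(r)) || any(r < 0)) stop("resistance must be finite and >= 0")
  cfg$u0_counts * cfg$r_ref / (cfg$r_ref + r)
}

#' Aggregate a burst of ADC reads into one resistance data point
#'
#' Converts each read to resistance and reports the mean, the standard error
#' of the mean (sample SD with `n - 1` denominator over `sqrt(n)`) and the
#' read count. This mirrors the device protocol of averaging 50 reads taken
#' at 50 ms intervals into a single data point.
#'
#' @param counts Numeric vector of ADC counts, all in `(0, u0_counts]`.
#' @param cfg A [detector_config()].
#' @param time_s Optional timestamp (seconds) attached to the data point.
#' @return A one-row data frame of class `ldr_measurement` with columns
#'   `time_s`, `r_mean_kohm`, `r_sem_kohm`, `n`.
#' @examples
#' aggregate_readings(rep(341, 50))
#' @export
aggregate_readings <- function(counts, cfg = detector_config(), time_s = NA_real_) {
  if (length(counts) == 0L) stop("empty read sequence")
  r <- counts_to_resistance(counts, cfg)
  n <- length(r)
  sem <- if (n > 1L) stats::sd(r) / sqrt(n) else 0
  structure(
    data.frame(time_s = time_s, r_mean_kohm = mean(r), r_sem_kohm = sem, n = n),
    class = c("ldr_measurement", "data.frame")
  )
}
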