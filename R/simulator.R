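#' Simulator configuration
#'
#' Ground truth and noise model for the synthetic detector. The simulated
#' chain is: concentration -> blank-normalised light intensity
#' `I = (1 + k*c)` (times a per-sample factor) -> LDR resistance
#' `R = rb * I^(-gamma)` (blank-anchored power law) -> first-order
#' equilibration lag from the dark state -> ideal divider counts ->
#' per-read multiplicative Gaussian count noise -> optional integer
#' quantization.
#'
#' Noise defaults reflect the reference device: 1% per-read count noise
#' (which, averaged over 50 reads, keeps the relative count SEM below the
#' 0.2% the acquisition protocol is designed for) and a 5% per-sample
#' intensity variability representing pipetting and paper-placement scatter,
#' matching the observed blank-resistance spread (a blank SD of ~93 kOhm on
#' 1650 kOhm is 5.7% in resistance, i.e. ~5.4% in intensity for
#' gamma near 1.05). Duplicate successive measurements of the same physical
#' sample share the sample draw.
#'
#' @param true_rb True blank resistance, kOhm.
#' @param true_k True slope constant, per nM.
#' @param true_gamma True LDR exponent.
#' @param count_noise_rel Relative SD of per-read multiplicative count noise.
#' @param sample_noise_rel Relative SD of the per-sample intensity factor
#'   (log-normal, `exp(N(0, sd))`).
#' @param ldr_tau_s LDR equilibration time constant, seconds. The default 3 s
#'   brings the sensor to equilibrium well within ~10 s.
#' @param seed Integer seed; identical configuration and seed give
#'   bit-identical output. `NULL` leaves the RNG stream untouched.
#' @param quantize Round simulated counts to integers (and clip to the ADC
#'   range) as the hardware does.
#' @return An object of class `ldr_simulator_config`.
#' @export
simulator_config <- function(true_rb = 1650, true_k = 0.0283,
                             true_gamma = 1.054, count_noise_rel = 0.01,
                             sample_noise_rel = 0.05, ldr_tau_s = 3,
                             seed = NULL, quantize = TRUE) {
  stopifnot(true_rb > 0, true_k > 0, true_gamma > 0,
            count_noise_rel >= 0, sample_noise_rel >= 0, ldr_tau_s > 0)
  structure(list(true_rb = true_rb, true_k = true_k, true_gamma = true_gamma,
                 count_noise_rel = count_noise_rel,
                 sample_noise_rel = sample_noise_rel,
                 ldr_tau_s = ldr_tau_s, seed = seed,
                 quantize = isTRUE(quantize)),
            class = "ldr_simulator_config")
}

# Run `expr` under the simulator's seed without disturbing the caller's RNG
# stream; with a NULL seed the global stream is used (and advanced).
with_sim_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Blank-normalised intensity at a given concentration
#'
#' The light reaching the sensor grows linearly with the fluorophore
#' concentration on top of the blank background: `I(c) = 1 + k*c` in units of
#' the blank intensity. Composed with the power law `R = rb * I^(-gamma)`
#' this reproduces [calibration_model()] exactly.
#'
#' @param c Concentration, nM.
#' @param k Slope constant, per nM.
#' @return Normalised intensity.
#' @export
intensity_from_concentration <- function(c, k) {
  if (any(c < 0)) stop("concentration must be >= 0")
  1 + k * c
}

# Deterministic part of one reading: equilibrating resistance at the read
# times, given the target resistance.
lagged_resistance <- function(r_target, sim, cfg) {
  t_read <- cfg$warmup_s +
    (seq_len(cfg$n_reads) - 1L) * cfg$read_interval_ms / 1000
  r_target + (cfg$dark_resistance - r_target) * exp(-t_read / sim$ldr_tau_s)
}

#' Simulate one burst of ADC reads
#'
#' Produces the `n_reads` ADC counts of a single data point for a sample of
#' concentration `c`: ideal resistance from the power-law response, first-
#' order equilibration from the dark state over the warm-up, multiplicative
#' Gaussian per-read noise on the counts, then optional quantization and
#' clipping to `[1, u0_counts]`.
#'
#' @param c Concentration, nM (scalar).
#' @param sim A [simulator_config()]; its `seed` (if non-`NULL`) makes the
#'   burst reproducible.
#' @param cfg A [detector_config()].
#' @param sample_factor Multiplicative intensity factor of this physical
#'   sample. `NULL` draws one from the configured `sample_noise_rel`; pass 1
#'   to disable, or re-use a factor across duplicate measurements of the same
#'   sample.
#' @return Numeric vector of `n_reads` counts (integers when quantizing).
#' @export
simulate_reading <- function(c, sim = simulator_config(),
                             cfg = detector_config(), sample_factor = NULL) {
  with_sim_seed(sim$seed, {
    if (is.null(sample_factor)) {
      sample_factor <- exp(stats::rnorm(1, 0, sim$sample_noise_rel))
    }
    intensity <- intensity_from_concentration(c, sim$true_k) * sample_factor
    r_target <- sim$true_rb * intensity^(-sim$true_gamma)
    r_t <- lagged_resistance(r_target, sim, cfg)
    u <- resistance_to_counts(r_t, cfg)
    u <- u * (1 + stats::rnorm(cfg$n_reads, 0, sim$count_noise_rel))
    if (sim$quantize) u <- pmin(pmax(round(u), 1), cfg$u0_counts)
    u
  })
}

#' Default calibration concentration ladder
#'
#' The 1-2-5 decade ladder used by the automated calibration routine:
#' 1, 2, 5, 10, 20, ... nM up to `c_max`.
#'
#' @param c_min Smallest concentration, nM.
#' @param c_max Largest concentration, nM.
#' @return Numeric vector of concentrations.
#' @examples
#' calibration_ladder()  # 1 nM ... 10000 nM
#' @export
calibration_ladder <- function(c_min = 1, c_max = 1e4) {
  decades <- 10^(floor(log10(c_min)):ceiling(log10(c_max)))
  grid <- sort(unique(as.vector(outer(c(1, 2, 5), decades))))
  grid[grid >= c_min & grid <= c_max]
}

#' Simulate a full calibration dilution series
#'
#' Emits the automated calibration sequence in acquisition order for each
#' replicate: a duplicated leading blank, the concentration ladder (each
#' sample measured `duplicates` times in direct succession), and a duplicated
#' trailing blank. Duplicate measurements re-measure the same physical sample
#' (shared sample-noise draw, fresh read noise); every measurement is
#' aggregated from `cfg$n_reads` simulated ADC reads.
#'
#' @param sim A [simulator_config()]; its `seed` governs the whole series.
#' @param cfg A [detector_config()].
#' @param grid Concentrations, nM (default [calibration_ladder()]).
#' @param replicates Number of independent dilution-series replicates.
#' @param duplicates Successive measurements per physical sample.
#' @return A data frame with one row per measurement and columns
#'   `concentration_nM`, `replicate`, `r_mean_kohm`, `r_sem_kohm`, `n`,
#'   `is_blank`, `sequence_index` — the input format of [ldr_calibrate()].
#' @examples
#' series <- simulate_dilution_series(simulator_config(seed = 1))
#' nrow(series)  # 3 * 2 * (13 + 2)
#' @export
simulate_dilution_series <- function(sim = simulator_config(),
                                     cfg = detector_config(),
                                     grid = calibration_ladder(),
                                     replicates = 3, duplicates = 2) {
  if (length(grid) == 0L) stop("empty concentration grid")
  with_sim_seed(sim$seed, {
    sim_inner <- sim; sim_inner$seed <- NULL
    rows <- list()
    for (rep_i in seq_len(replicates)) {
      seq_conc <- c(0, grid, 0)               # leading blank, ladder, trailing blank
      seq_blank <- c(TRUE, rep(FALSE, length(grid)), TRUE)
      idx <- 0L
      for (s in seq_along(seq_conc)) {
        f <- exp(stats::rnorm(1, 0, sim$sample_noise_rel))
        for (d in seq_len(duplicates)) {
          idx <- idx + 1L
          counts <- simulate_reading(seq_conc[s], sim_inner, cfg,
                                     sample_factor = f)
          m <- aggregate_readings(counts, cfg)
          rows[[length(rows) + 1L]] <- data.frame(
            concentration_nM = seq_conc[s], replicate = rep_i,
            r_mean_kohm = m$r_mean_kohm, r_sem_kohm = m$r_sem_kohm, n = m$n,
            is_blank = seq_blank[s], sequence_index = idx)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Assay time-trace specification
#'
#' Concentration-versus-time profiles of the emulated on-paper assays:
#' \describe{
#'   \item{`fluorescein_constant`}{constant concentration `c0`.}
#'   \item{`ispinach_transcription`}{fluorogenic-aptamer transcription,
#'     saturating rise `c(t) = amplitude * (1 - exp(-rate * t))`; the initial
#'     rate `amplitude * rate` scales with the DNA template concentration.}
#'   \item{`cas13a`}{collateral-cleavage reporter release, same saturating
#'     form; a cognate target gives a fast rate, a non-cognate target only a
#'     slow background rate.}
#' }
#'
#' @param kind One of `"fluorescein_constant"`, `"ispinach_transcription"`,
#'   `"cas13a"`.
#' @param c0 Constant concentration (nM), for `fluorescein_constant`.
#' @param amplitude Plateau concentration (nM), for the kinetic kinds.
#' @param rate First-order rate constant, per minute.
#' @param duration_min Trace duration, minutes.
#' @param interval_s Spacing between data points, seconds.
#' @return An object of class `ldr_assay_spec`.
#' @export
assay_trace_spec <- function(kind = c("fluorescein_constant",
                                      "ispinach_transcription", "cas13a"),
                             c0 = 100, amplitude = 200, rate = 0.05,
                             duration_min = 60, interval_s = 60) {
  kind <- match.arg(kind)
  stopifnot(c0 >= 0, amplitude >= 0, rate >= 0, duration_min > 0,
            interval_s > 0)
  structure(list(kind = kind, c0 = c0, amplitude = amplitude, rate = rate,
                 duration_min = duration_min, interval_s = interval_s),
            class = "ldr_assay_spec")
}

# Concentration trajectory of a trace spec at times t (seconds).
trace_concentration <- function(spec, time_s) {
  t_min <- time_s / 60
  switch(spec$kind,
         fluorescein_constant = rep(spec$c0, length(time_s)),
         ispinach_transcription = spec$amplitude * (1 - exp(-spec$rate * t_min)),
         cas13a = spec$amplitude * (1 - exp(-spec$rate * t_min)),
         stop("unknown assay kind: ", spec$kind))
}

#' Simulate an assay time trace
#'
#' Generates the aggregated resistance measurement at every requested time
#' point of an assay trajectory. The whole trace is measured on one physical
#' sample, so a single sample-noise draw applies throughout.
#'
#' @param spec An [assay_trace_spec()].
#' @param sim A [simulator_config()].
#' @param cfg A [detector_config()].
#' @param raw If `TRUE`, return one row per individual ADC read
#'   (columns `time_s`, `counts`) instead of aggregated data points.
#' @return A data frame: aggregated (`time_s`, `r_mean_kohm`, `r_sem_kohm`,
#'   `n`) by default, with the true concentrations in attribute `"c_true"`.
#' @export
simulate_assay_trace <- function(spec, sim = simulator_config(),
                                 cfg = detector_config(), raw = FALSE) {
  times <- seq(0, spec$duration_min * 60, by = spec$interval_s)
  conc <- trace_concentration(spec, times)
  with_sim_seed(sim$seed, {
    sim_inner <- sim; sim_inner$seed <- NULL
    f <- exp(stats::rnorm(1, 0, sim$sample_noise_rel))
    out <- vector("list", length(times))
    for (i in seq_along(times)) {
      counts <- simulate_reading(conc[i], sim_inner, cfg, sample_factor = f)
      out[[i]] <- if (raw) {
        data.frame(time_s = times[i], counts = counts)
      } else {
        m <- aggregate_readings(counts, cfg, time_s = times[i])
        as.data.frame(m)
      }
    }
    res <- do.call(rbind, out)
    attr(res, "c_true") <- conc
    res
  })
}
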