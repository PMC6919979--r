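#' Systematic concentration uncertainty budget
#'
#' First-order (Gaussian) propagation of the instrument and calibration
#' uncertainties to the inferred concentration. Writing the measurement chain
#' as `R = r_ref * (u0/u - 1)` (voltage divider) followed by
#' `c = ((R/Rb)^(-1/gamma) - 1) / k` (inverted calibration), the considered
#' one-sigma sources are:
#' \itemize{
#'   \item `u_ldr`: the one-digit ADC accuracy of the divider reading,
#'   \item `u0`: the one-digit ADC accuracy of the supply reading,
#'   \item `rb`: the blank-resistance uncertainty `d_rb`,
#'   \item `k`, `gamma`: the asymptotic standard errors of the fit.
#' }
#' Sources are treated as independent; the total is their root sum of
#' squares. With `y = 1 + k*c` the partial derivatives are
#' `|dc/dR| = y^(1+gamma)/(k*gamma*Rb)`, `|dc/dRb| = y/(k*gamma*Rb)`,
#' `|dc/dk| = c/k`, `|dc/dgamma| = y*log(y)/(k*gamma)`, and the digit errors
#' map into resistance via `|dR/du| = r_ref*u0/u^2`, `|dR/du0| = r_ref/u`.
#'
#' The resulting relative uncertainty is U-shaped in `c`: it diverges toward
#' the blank (the absolute floor set by `d_rb` and the ADC digit dominates a
#' vanishing `c`) and grows again at high `c` where the divider saturates and
#' the `k`/`gamma` errors are amplified.
#'
#' @param c Concentration in nM, `> 0`. Vectorized.
#' @param params A [calibration_params()] (or `ldr_cal` fit).
#' @param cfg A [detector_config()]; supplies `r_ref`, the ADC full scale and
#'   the digit uncertainty.
#' @return A data frame of class `ldr_unc_budget` with the concentration, the
#'   per-source relative contributions (`rel_u_ldr`, `rel_u0`, `rel_rb`,
#'   `rel_k`, `rel_gamma`), the total `rel_total` and the absolute `dc_nM`.
#' @examples
#' concentration_uncertainty(c(10, 100, 1000), calibration_params())
#' @export
concentration_uncertainty <- function(c, params = calibration_params(),
                                      cfg = detector_config()) {
  params <- as_calibration_params(params)
  if (any(c <= 0)) stop("concentration must be > 0 for a relative uncertainty")
  k <- params$k; g <- params$gamma; rb <- params$rb
  y <- 1 + k * c
  ratio <- y^(-g)
  r <- rb * ratio
  u <- cfg$u0_counts * cfg$r_ref / (cfg$r_ref + r)
  du <- cfg$delta_u_counts
  dr_u  <- cfg$r_ref * cfg$u0_counts / u^2 * du
  dr_u0 <- cfg$r_ref / u * du
  dc_dr  <- y^(1 + g) / (k * g * rb)
  dc_drb <- y / (k * g * rb)
  dc_dk  <- c / k
  dc_dg  <- y * log(y) / (k * g)
  a_u   <- dc_dr * dr_u
  a_u0  <- dc_dr * dr_u0
  a_rb  <- dc_drb * params$d_rb
  a_k   <- dc_dk * params$d_k
  a_g   <- dc_dg * params$d_gamma
  dc <- sqrt(a_u^2 + a_u0^2 + a_rb^2 + a_k^2 + a_g^2)
  structure(
    data.frame(c_nM = c,
               rel_u_ldr = a_u / c, rel_u0 = a_u0 / c, rel_rb = a_rb / c,
               rel_k = a_k / c, rel_gamma = a_g / c,
               rel_total = dc / c, dc_nM = dc),
    class = c("ldr_unc_budget", "data.frame"))
}

#' Confident measurement range
#'
#' The contiguous concentration interval over which the total relative
#' systematic uncertainty [concentration_uncertainty()] stays at or below a
#' threshold (15% by default). The budget is evaluated on a logarithmic grid;
#' the interval containing the minimum of the curve is kept and its
#' boundaries are refined by root bracketing to about three significant
#' digits. If the curve never drops below the threshold an empty range
#' (`c(NA, NA)`) is returned with attribute `empty = TRUE`.
#'
#' @param params A [calibration_params()] (or `ldr_cal` fit).
#' @param cfg A [detector_config()].
#' @param threshold Relative-uncertainty threshold, a fraction in `(0, 1)`.
#' @param domain Search interval in nM.
#' @param n_grid Number of log-spaced grid points.
#' @return Length-2 numeric `c(c_lo, c_hi)` in nM, attributes `threshold` and
#'   `empty`. Boundaries coinciding with the search domain edges are returned
#'   as the edges themselves.
#' @examples
#' confident_range(calibration_params(), detector_config())
#' @export
confident_range <- function(params = calibration_params(),
                            cfg = detector_config(), threshold = 0.15,
                            domain = c(1e-2, 1e6), n_grid = 2000) {
  stopifnot(threshold > 0, threshold < 1, length(domain) == 2L,
            domain[1] > 0, domain[2] > domain[1])
  params <- as_calibration_params(params)
  grid <- 10^seq(log10(domain[1]), log10(domain[2]), length.out = n_grid)
  f <- function(c) concentration_uncertainty(c, params, cfg)$rel_total - threshold
  val <- f(grid)
  below <- val <= 0
  if (!any(below)) {
    return(structure(c(NA_real_, NA_real_), threshold = threshold, empty = TRUE))
  }
  # contiguous run containing the minimum of the curve
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  imin <- which.min(val)
  run <- which(runs$values & starts <= imin & ends >= imin)
  if (length(run) == 0L) run <- which(runs$values)[1]
  i1 <- starts[run]; i2 <- ends[run]
  refine <- function(ia, ib) {
    # bisection on log10(c) between bracketing grid points
    stats::uniroot(function(l) f(10^l), lower = log10(grid[ia]),
                   upper = log10(grid[ib]), tol = 1e-4)$root
  }
  lo <- if (i1 == 1L) domain[1] else 10^refine(i1 - 1L, i1)
  hi <- if (i2 == n_grid) domain[2] else 10^refine(i2, i2 + 1L)
  structure(c(lo, hi), threshold = threshold, empty = FALSE)
}

#' IUPAC detection and quantification limits
#'
#' Following the IUPAC convention, the limit of detection (LOD) is the blank
#' level shifted by 3 standard deviations of the blank measurements and the
#' limit of quantification (LOQ) by 10. Because fluorescence *lowers* the LDR
#' resistance, the thresholds lie *below* the blank:
#' `LOD_R = rb - 3*sigma`, `LOQ_R = rb - 10*sigma`. Both are converted to
#' concentrations through [invert_calibration()].
#'
#' `sigma` is the sample standard deviation of the blank mean-resistances. If
#' raw blank measurements are not supplied it is reconstructed from the
#' parameters as `d_rb * sqrt(n_blanks)` (SEM times root-N).
#'
#' @param params A [calibration_params()] (or `ldr_cal` fit).
#' @param blanks Optional blank measurements: a numeric vector of blank mean
#'   resistances (kOhm) or a data frame with a `r_mean_kohm` column.
#' @param sigma Optional blank standard deviation (kOhm), overriding both of
#'   the above.
#' @return An object of class `ldr_limits`: list with `rb`, `sigma`,
#'   `lod_resistance`, `loq_resistance` (kOhm), `lod_concentration`,
#'   `loq_concentration` (nM).
#' @examples
#' detection_limits(calibration_params())  # sigma = 22 * sqrt(18)
#' @export
detection_limits <- function(params = calibration_params(), blanks = NULL,
                             sigma = NULL) {
  params <- as_calibration_params(params)
  if (is.null(sigma)) {
    if (!is.null(blanks)) {
      b <- if (is.data.frame(blanks)) blanks$r_mean_kohm else as.numeric(blanks)
      if (length(b) < 2L) stop("need at least 2 blank measurements")
      sigma <- stats::sd(b)
    } else {
      sigma <- params$d_rb * sqrt(params$n_blanks)
    }
  }
  rb <- params$rb
  if (sigma == 0) {
    warning("degenerate blanks (sigma = 0): LOD = LOQ = Rb, concentration 0")
  }
  lod_r <- rb - 3 * sigma
  loq_r <- rb - 10 * sigma
  to_conc <- function(r) {
    if (r <= 0) return(Inf)  # threshold beyond the divider's range
    as.numeric(invert_calibration(r, params))
  }
  structure(list(rb = rb, sigma = sigma,
                 lod_resistance = lod_r, loq_resistance = loq_r,
                 lod_concentration = to_conc(lod_r),
                 loq_concentration = to_conc(loq_r)),
            class = "ldr_limits")
}

#' @export
print.ldr_limits <- function(x, ...) {
  cat("IUPAC detection limits (blank-referenced)\n")
  cat(sprintf("  Rb = %.4g kOhm, sigma(blanks) = %.3g kOhm\n", x$rb, x$sigma))
  cat(sprintf("  LOD: %.4g kOhm  =  %.3g nM\n",
              x$lod_resistance, x$lod_concentration))
  cat(sprintf("  LOQ: %.4g kOhm  =  %.3g nM\n",
              x$loq_resistance, x$loq_concentration))
  invisible(x)
}

#' Monte-Carlo check of the analytic uncertainty budget
#'
#' Independent cross-check of [concentration_uncertainty()]: draws Gaussian
#' perturbations of the ADC readings (divider and supply), the blank
#' resistance and the calibration parameters, pushes each draw through the
#' divider equation and the inverted calibration, and reports the relative
#' standard deviation of the recovered concentrations.
#'
#' @param c True concentration, nM (scalar).
#' @param params A [calibration_params()].
#' @param cfg A [detector_config()].
#' @param n_draws Number of Monte-Carlo draws.
#' @return Relative standard deviation of the recovered concentration.
#' @export
mc_concentration_uncertainty <- function(c, params = calibration_params(),
                                         cfg = detector_config(),
                                         n_draws = 1e5) {
  params <- as_calibration_params(params)
  r_true <- params$rb * calibration_model(c, params$k, params$gamma)
  u_true <- resistance_to_counts(r_true, cfg)
  du <- cfg$delta_u_counts
  u  <- u_true + stats::rnorm(n_draws, 0, du)
  u0 <- cfg$u0_counts + stats::rnorm(n_draws, 0, du)
  rb <- params$rb + stats::rnorm(n_draws, 0, params$d_rb)
  k  <- params$k + stats::rnorm(n_draws, 0, params$d_k)
  g  <- params$gamma + stats::rnorm(n_draws, 0, params$d_gamma)
  r  <- cfg$r_ref * (u0 / u - 1)
  cc <- ((r / rb)^(-1 / g) - 1) / k
  stats::sd(cc) / c
}
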