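#' Power-law calibration model for relative resistance
#'
#' The LDR resistance follows `R = A * I^(-gamma)` in the incident light
#' intensity `I`, and on-paper fluorescence adds light linearly in the
#' fluorophore concentration, `I(c) = I_blank * (1 + k * c)`. Normalising by
#' the blank gives the calibration function
#' \deqn{R(c)/R_b = (1 + k c)^{-\gamma}.}
#' It equals 1 at `c = 0` and decreases strictly in `c`.
#'
#' @param c Concentration in nM, `>= 0`. Vectorized.
#' @param k Slope constant, per nM. Captures LED/filter/fluorophore/LDR
#'   spectral overlap and scattering; independent of excitation intensity.
#' @param gamma Dimensionless LDR exponent.
#' @return Relative resistance `R(c)/R_b` (dimensionless).
#' @examples
#' calibration_model(100, k = 0.0283, gamma = 1.054)
#' @export
calibration_model <- function(c, k, gamma) {
  if (any(c < 0, na.rm = TRUE)) stop("concentration must be >= 0")
  base <- 1 + k * c
  if (any(base <= 0, na.rm = TRUE)) stop("1 + k*c <= 0: outside model domain")
  base^(-gamma)
}

#' Invert the calibration model: resistance to concentration
#'
#' Algebraic inverse of [calibration_model()]:
#' `c = ((r / rb)^(-1/gamma) - 1) / k`. Resistances above the blank would map
#' to negative concentrations; these are clipped to 0 and flagged (blank drift
#' is reported, not hidden).
#'
#' @param r Measured resistance in kOhm, `> 0`. Vectorized.
#' @param params A [calibration_params()] (or an `ldr_cal` fit).
#' @return Concentration in nM, with a logical attribute `"out_of_range"`
#'   marking entries where `r > rb` was clipped to 0.
#' @examples
#' p <- calibration_params()
#' invert_calibration(1372, p)  # about 6.8 nM
#' @export
invert_calibration <- function(r, params) {
  params <- as_calibration_params(params)
  if (any(!is.finite(r)) || any(r <= 0)) stop("resistance must be finite and > 0")
  high <- r > params$rb
  rr <- pmin(r, params$rb)
  conc <- ((rr / params$rb)^(-1 / params$gamma) - 1) / params$k
  conc[high] <- 0
  if (any(high)) {
    warning(sprintf("%d resistance value(s) above the blank Rb; clipped to c = 0",
                    sum(high)))
  }
  attr(conc, "out_of_range") <- high
  conc
}

#' Calibration parameters
#'
#' Container for a fitted (or externally supplied) calibration: blank
#' resistance `rb`, slope constant `k` and LDR exponent `gamma`, each with a
#' one-sigma uncertainty, plus the number of blank measurements behind `rb`.
#' Defaults are the reference fluorescein calibration of the reader.
#'
#' @param rb Blank resistance, kOhm.
#' @param d_rb Standard error of `rb` (SEM over the blank measurements), kOhm.
#' @param k Slope constant, per nM.
#' @param d_k Asymptotic standard error of `k`, per nM.
#' @param gamma LDR exponent (dimensionless).
#' @param d_gamma Asymptotic standard error of `gamma`.
#' @param n_blanks Number of blank measurements pooled into `rb`.
#' @return An object of class `ldr_cal_params`.
#' @examples
#' calibration_params()
#' @export
calibration_params <- function(rb = 1650, d_rb = 22, k = 0.0283, d_k = 0.0010,
                               gamma = 1.054, d_gamma = 0.019, n_blanks = 18) {
  stopifnot(rb > 0, k > 0, gamma > 0,
            d_rb >= 0, d_k >= 0, d_gamma >= 0, n_blanks >= 1)
  structure(list(rb = rb, d_rb = d_rb, k = k, d_k = d_k,
                 gamma = gamma, d_gamma = d_gamma,
                 n_blanks = as.integer(n_blanks)),
            class = "ldr_cal_params")
}

#' Coerce to calibration parameters
#'
#' @param x An `ldr_cal_params` object, an `ldr_cal` fit, or a named list with
#'   fields `rb`, `k`, `gamma` (uncertainties optional, defaulting to 0).
#' @return An `ldr_cal_params` object.
#' @export
as_calibration_params <- function(x) {
  if (inherits(x, "ldr_cal_params")) return(x)
  if (inherits(x, "ldr_cal")) return(x$params)
  if (is.list(x) && all(c("rb", "k", "gamma") %in% names(x))) {
    return(calibration_params(
      rb = x$rb, d_rb = if (is.null(x$d_rb)) 0 else x$d_rb,
      k = x$k, d_k = if (is.null(x$d_k)) 0 else x$d_k,
      gamma = x$gamma, d_gamma = if (is.null(x$d_gamma)) 0 else x$d_gamma,
      n_blanks = if (is.null(x$n_blanks)) 1 else x$n_blanks))
  }
  stop("cannot interpret 'params' as calibration parameters")
}

#' @export
print.ldr_cal_params <- function(x, ...) {
  cat("Calibration parameters\n")
  cat(sprintf("  Rb    = %.4g +/- %.3g kOhm (N = %d blanks)\n",
              x$rb, x$d_rb, x$n_blanks))
  cat(sprintf("  k     = %.4g +/- %.3g /nM\n", x$k, x$d_k))
  cat(sprintf("  gamma = %.4g +/- %.3g\n", x$gamma, x$d_gamma))
  invisible(x)
}

# Split a dilution-series data frame into blank and sample records, with the
# basic schema checks shared by relative_resistance() and ldr_calibrate().
check_series <- function(series) {
  need <- c("concentration_nM", "r_mean_kohm", "r_sem_kohm", "is_blank")
  miss <- setdiff(need, names(series))
  if (length(miss)) {
    stop("dilution series is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!"n" %in% names(series)) series$n <- NA_integer_
  series$is_blank <- as.logical(series$is_blank)
  if (any(series$concentration_nM < 0)) stop("negative concentration in series")
  if (!any(series$is_blank)) stop("dilution series contains no blank measurements")
  series
}

#' Relative resistance table from a dilution series
#'
#' Pools all blank measurements into the blank resistance `rb` (mean) and its
#' SEM, then expresses every sample measurement as a ratio `R(c)/Rb` with a
#' first-order Gaussian uncertainty
#' `d(R/Rb) = (R/Rb) * sqrt((dR/R)^2 + (dRb/Rb)^2)`.
#'
#' @param series Data frame with columns `concentration_nM`, `r_mean_kohm`,
#'   `r_sem_kohm`, `n`, `is_blank` (and optionally `replicate`,
#'   `sequence_index`), as produced by [simulate_dilution_series()] or read
#'   from a calibration CSV.
#' @return A data frame with columns `concentration_nM`, `ratio`, `d_ratio`
#'   (one row per non-blank measurement), carrying attributes `rb`, `d_rb`
#'   and `n_blanks`.
#' @export
relative_resistance <- function(series) {
  series <- check_series(series)
  blanks <- series[series$is_blank, , drop = FALSE]
  rb <- mean(blanks$r_mean_kohm)
  n_blanks <- nrow(blanks)
  d_rb <- if (n_blanks > 1L) stats::sd(blanks$r_mean_kohm) / sqrt(n_blanks) else 0
  samp <- series[!series$is_blank, , drop = FALSE]
  ratio <- samp$r_mean_kohm / rb
  rel_r <- ifelse(samp$r_mean_kohm > 0, samp$r_sem_kohm / samp$r_mean_kohm, 0)
  rel_rb <- if (rb > 0) d_rb / rb else 0
  out <- data.frame(concentration_nM = samp$concentration_nM,
                    ratio = ratio,
                    d_ratio = ratio * sqrt(rel_r^2 + rel_rb^2))
  attr(out, "rb") <- rb
  attr(out, "d_rb") <- d_rb
  attr(out, "n_blanks") <- n_blanks
  out
}

#' Fit the calibration model to a dilution series
#'
#' The central fitting function of the package. Computes the relative
#' resistance table with [relative_resistance()], then fits
#' `ratio ~ (1 + k*c)^(-gamma)` by weighted nonlinear least squares with
#' weights `1/d_ratio^2` (inverse variance). Asymptotic standard errors of
#' `k` and `gamma` are scaled by the square root of the reduced chi-square,
#' the convention of common fitting tools, so that residual scatter beyond
#' the per-point uncertainties inflates the reported errors.
#'
#' Initialisation: `gamma = 1`, and `k` from the slope of
#' `log(ratio) ~ -gamma * k * c` over the three smallest concentrations.
#' If any per-point uncertainty is zero the fit falls back to unweighted
#' least squares with a warning.
#'
#' @param series A dilution-series data frame (see [relative_resistance()]).
#'   All measurements — including duplicate successive reads of one sample —
#'   enter the fit as independent observations.
#' @param start Optional named list overriding the automatic starting values,
#'   e.g. `list(k = 0.05, gamma = 1.2)`.
#' @param control Passed to [minpack.lm::nls.lm.control()]-style control via
#'   `nlsLM`; default raises the iteration cap.
#' @return An object of class `ldr_cal` with components `params`
#'   (an [calibration_params()] object), `fit` (the underlying `nls` object),
#'   `table` (the relative-resistance table), `chi2_red` (reduced chi-square
#'   of the weighted fit), `n_points`, `weighted` and `data` (the input
#'   series). Supports `print`, `summary`, `coef`, `vcov`, `predict`, `plot`,
#'   `residuals` and `simulate`.
#' @examples
#' sim <- simulator_config(seed = 42)
#' series <- simulate_dilution_series(sim)
#' cal <- ldr_calibrate(series)
#' coef(cal)
#' @export
ldr_calibrate <- function(series, start = NULL,
                          control = stats::nls.control(maxiter = 200)) {
  tab <- relative_resistance(series)
  if (length(unique(tab$concentration_nM)) < 3L) {
    stop("need at least 3 distinct non-blank concentrations to fit")
  }
  weighted <- all(tab$d_ratio > 0)
  if (!weighted) {
    warning("zero per-point uncertainties present; falling back to unweighted fit")
  }
  if (is.null(start)) {
    # log-linearised slope over the three smallest concentrations, gamma = 1
    cs <- sort(unique(tab$concentration_nM))[seq_len(min(3L, length(unique(tab$concentration_nM))))]
    sm <- tab[tab$concentration_nM %in% cs & tab$ratio > 0, , drop = FALSE]
    sl <- stats::coef(stats::lm(log(sm$ratio) ~ sm$concentration_nM))[2]
    start <- list(k = max(abs(sl), 1e-6), gamma = 1)
  }
  w <- if (weighted) 1 / tab$d_ratio^2 else rep(1, nrow(tab))
  fit <- tryCatch(
    minpack.lm::nlsLM(ratio ~ (1 + k * concentration_nM)^(-gamma),
                      data = tab, start = start, weights = w,
                      lower = c(k = 1e-12, gamma = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop("calibration fit did not converge (start: k = ",
           signif(start$k, 4), ", gamma = ", signif(start$gamma, 4), "): ",
           conditionMessage(e))
    }
  )
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  dof <- nrow(tab) - 2L
  chi2_red <- sum(w * stats::residuals(fit)^2) / dof
  params <- calibration_params(
    rb = attr(tab, "rb"), d_rb = attr(tab, "d_rb"),
    k = est[["k"]], d_k = se[["k"]],
    gamma = est[["gamma"]], d_gamma = se[["gamma"]],
    n_blanks = attr(tab, "n_blanks"))
  structure(list(params = params, fit = fit, table = tab,
                 chi2_red = chi2_red, n_points = nrow(tab),
                 weighted = weighted, data = series,
                 call = match.call()),
            class = "ldr_cal")
}
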