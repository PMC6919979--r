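#' @export
print.ldr_cal <- function(x, ...) {
  cat("LDR fluorescence calibration fit\n")
  cat(sprintf("  %d points, %s least squares, reduced chi-square %.3g\n",
              x$n_points, if (x$weighted) "inverse-variance weighted" else
                "unweighted", x$chi2_red))
  print(x$params)
  invisible(x)
}

#' @export
coef.ldr_cal <- function(object, ...) {
  with(object$params, c(rb = rb, k = k, gamma = gamma))
}

#' Variance-covariance matrix of the fitted calibration
#'
#' Covariance of `(k, gamma)` from the weighted fit (scaled by the reduced
#' chi-square, as for the reported standard errors), extended with the
#' independently estimated blank variance `d_rb^2`; `rb` is estimated from
#' the blanks, not by the fit, so its covariances with `k` and `gamma` are
#' zero by construction.
#'
#' @param object An `ldr_cal` fit.
#' @param ... Unused.
#' @return A 3x3 matrix over `(rb, k, gamma)`.
#' @export
vcov.ldr_cal <- function(object, ...) {
  v <- matrix(0, 3, 3, dimnames = list(c("rb", "k", "gamma"),
                                       c("rb", "k", "gamma")))
  v["rb", "rb"] <- object$params$d_rb^2
  v[c("k", "gamma"), c("k", "gamma")] <- stats::vcov(object$fit)
  v
}

#' @export
summary.ldr_cal <- function(object, cfg = detector_config(),
                            threshold = 0.15, ...) {
  lim <- detection_limits(object$params)
  rng <- confident_range(object$params, cfg, threshold = threshold)
  structure(list(cal = object, limits = lim, range = rng,
                 threshold = threshold), class = "summary.ldr_cal")
}

#' @export
print.summary.ldr_cal <- function(x, ...) {
  print(x$cal)
  print(x$limits)
  cat(sprintf("  confident range (delta_c/c <= %g%%): %s - %s nM\n",
              100 * x$threshold, signif(x$range[1], 3), signif(x$range[2], 3)))
  invisible(x)
}

#' Predict from a fitted calibration
#'
#' @param object An `ldr_cal` fit.
#' @param newdata Concentrations in nM (for `type` `"ratio"`/`"resistance"`)
#'   or resistances in kOhm (for `type = "concentration"`). Defaults to the
#'   concentrations used in the fit.
#' @param type `"ratio"` returns `R(c)/Rb`, `"resistance"` returns `R(c)` in
#'   kOhm, `"concentration"` inverts the calibration.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.ldr_cal <- function(object, newdata = NULL,
                            type = c("ratio", "resistance", "concentration"),
                            ...) {
  type <- match.arg(type)
  p <- object$params
  if (type == "concentration") {
    if (is.null(newdata)) stop("supply resistances in 'newdata' for type = 'concentration'")
    return(invert_calibration(newdata, p))
  }
  if (is.null(newdata)) newdata <- object$table$concentration_nM
  ratio <- calibration_model(newdata, p$k, p$gamma)
  if (type == "resistance") ratio * p$rb else ratio
}

#' @export
residuals.ldr_cal <- function(object, type = c("weighted", "raw"), ...) {
  type <- match.arg(type)
  r <- object$table$ratio - predict(object, object$table$concentration_nM)
  if (type == "weighted" && object$weighted) r <- r / object$table$d_ratio
  r
}

#' Plot a fitted calibration
#'
#' Relative resistance against concentration on a log axis, with per-point
#' error bars and the fitted curve; optionally a second panel with the
#' propagated relative concentration uncertainty and the confident range.
#'
#' @param x An `ldr_cal` fit.
#' @param cfg A [detector_config()] (used for the uncertainty panel).
#' @param uncertainty If `TRUE`, add the relative-uncertainty panel.
#' @param threshold Confident-range threshold shown in the uncertainty panel.
#' @param ... Passed to `plot`.
#' @return Invisibly, `x`.
#' @export
plot.ldr_cal <- function(x, cfg = detector_config(), uncertainty = FALSE,
                         threshold = 0.15, ...) {
  tab <- x$table
  if (uncertainty) {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  grid <- 10^seq(log10(max(min(tab$concentration_nM), 1e-3)),
                 log10(max(tab$concentration_nM)), length.out = 200)
  plot(tab$concentration_nM, tab$ratio, log = "x",
       xlab = "concentration [nM]", ylab = expression(R(c) / R[b]), ...)
  graphics::arrows(tab$concentration_nM, tab$ratio - tab$d_ratio,
                   tab$concentration_nM, tab$ratio + tab$d_ratio,
                   angle = 90, code = 3, length = 0.02)
  graphics::lines(grid, predict(x, grid), col = "firebrick")
  if (uncertainty) {
    u <- concentration_uncertainty(grid, x$params, cfg)
    plot(grid, 100 * u$rel_total, log = "xy", type = "l",
         xlab = "concentration [nM]", ylab = "relative uncertainty [%]")
    graphics::abline(h = 100 * threshold, lty = 2)
  }
  invisible(x)
}

#' Simulate dilution series from a fitted calibration
#'
#' Draws new synthetic calibration data sets whose ground truth is the fitted
#' `(rb, k, gamma)`, using the package's detector simulator. Follows the
#' `simulate` generic convention: returns a list of `nsim` data frames.
#'
#' @param object An `ldr_cal` fit.
#' @param nsim Number of series to generate.
#' @param seed Seed for the simulator (offset by the series index).
#' @param cfg A [detector_config()].
#' @param ... Passed to [simulator_config()] (noise settings etc.).
#' @return A list of `nsim` dilution-series data frames.
#' @export
simulate.ldr_cal <- function(object, nsim = 1, seed = NULL,
                             cfg = detector_config(), ...) {
  p <- object$params
  grid <- sort(unique(object$table$concentration_nM))
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    sim <- simulator_config(true_rb = p$rb, true_k = p$k, true_gamma = p$gamma,
                            seed = if (is.null(seed)) NULL else seed + i - 1L,
                            ...)
    out[[i]] <- simulate_dilution_series(sim, cfg, grid = grid)
  }
  out
}
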