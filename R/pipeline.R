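#' Read and write the package's CSV dialects
#'
#' Plain-CSV formats used by the reader software and this package:
#' \describe{
#'   \item{raw trace}{`time_s,counts` — one row per ADC read.}
#'   \item{aggregated trace}{`time_s,r_mean_kohm,r_sem_kohm,n` — one row per
#'     data point.}
#'   \item{dilution series}{`concentration_nM,replicate,r_mean_kohm,
#'     r_sem_kohm,n,is_blank,sequence_index`.}
#' }
#' Numbers are written with full precision (15 significant digits), so a
#' write/read round trip is lossless to better than 1e-9 relative.
#'
#' @param path File path.
#' @param x Data frame to write.
#' @return The data frame (readers), or invisibly the path (writers).
#' @name ldr_csv
NULL

write_ldr_csv <- function(x, path) {
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], function(v) formatC(v, digits = 15, format = "g"))
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname ldr_csv
#' @export
read_dilution_series <- function(path) {
  x <- utils::read.csv(path)
  check_series(x)
}

#' @rdname ldr_csv
#' @export
write_dilution_series <- function(x, path) write_ldr_csv(x, path)

#' @rdname ldr_csv
#' @export
read_trace <- function(path) {
  x <- utils::read.csv(path)
  if (!("counts" %in% names(x) || "r_mean_kohm" %in% names(x))) {
    stop("trace CSV must contain either a 'counts' (raw) or 'r_mean_kohm' ",
         "(aggregated) column")
  }
  x
}

#' @rdname ldr_csv
#' @export
write_trace <- function(x, path) write_ldr_csv(x, path)

#' Write / read a calibration as JSON
#'
#' The calibration document carries the five parameters with uncertainties,
#' blank bookkeeping and fit diagnostics, and is the file consumed by the
#' quantification commands.
#'
#' @param cal An `ldr_cal` fit, `ldr_cal_params`, or a calibration report
#'   from [run_calibration_workflow()].
#' @param path Output path.
#' @return Invisibly the path; `read_calibration_json()` returns an
#'   `ldr_cal_params` object with extra fields (diagnostics, limits) in
#'   attribute `"report"` when present.
#' @export
write_calibration_json <- function(cal, path) {
  doc <- if (inherits(cal, "ldr_cal_report")) {
    cal$json
  } else if (inherits(cal, "ldr_cal")) {
    c(unclass(cal$params),
      list(chi2_red = cal$chi2_red, n_points = cal$n_points))
  } else {
    unclass(as_calibration_params(cal))
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- as_calibration_params(doc)
  attr(p, "report") <- doc
  p
}

# Aggregate a raw trace (one row per read) into data points by timestamp.
aggregate_trace <- function(trace, cfg) {
  pts <- lapply(split(trace, trace$time_s), function(d) {
    aggregate_readings(d$counts, cfg, time_s = d$time_s[1])
  })
  out <- do.call(rbind, pts)
  out[order(out$time_s), , drop = FALSE]
}

#' Quantify a measured time trace
#'
#' Converts a raw or aggregated resistance trace into concentration
#' estimates. Per data point: aggregate the reads (if raw), invert the
#' calibration, attach the total uncertainty — the systematic budget of
#' [concentration_uncertainty()] combined in quadrature with the statistical
#' contribution of the point's own SEM — and flag the estimate against the
#' IUPAC limits and the confident range.
#'
#' Flags are assigned in resistance space, where they are well-defined even
#' for points at or above the blank: `below_lod` when the resistance lies
#' above the LOD threshold, `below_loq` likewise, `out_of_range` when the
#' resistance exceeds the blank (concentration clipped to 0).
#'
#' @param trace Data frame: raw (`time_s`, `counts`) or aggregated
#'   (`time_s`, `r_mean_kohm`, `r_sem_kohm`, `n`); or a path to such a CSV.
#' @param params A [calibration_params()] (or `ldr_cal` fit).
#' @param cfg A [detector_config()].
#' @param limits Optional [detection_limits()] result (computed from
#'   `params` if omitted).
#' @param range Optional [confident_range()] result (computed if omitted).
#' @return A data frame of class `ldr_trace` with columns `time_s`,
#'   `r_mean_kohm`, `r_sem_kohm`, `n`, `c_nM`, `dc_nM`, `dc_rel`,
#'   `below_lod`, `below_loq`, `in_confident_range`, `out_of_range`.
#' @export
quantify_timetrace <- function(trace, params = calibration_params(),
                               cfg = detector_config(), limits = NULL,
                               range = NULL) {
  params <- as_calibration_params(params)
  if (is.character(trace)) trace <- read_trace(trace)
  if (nrow(trace) == 0L) stop("empty trace")
  if (!"r_mean_kohm" %in% names(trace)) trace <- aggregate_trace(trace, cfg)
  if (!"r_sem_kohm" %in% names(trace)) trace$r_sem_kohm <- 0
  if (!"n" %in% names(trace)) trace$n <- NA_integer_
  if (is.null(limits)) limits <- detection_limits(params)
  if (is.null(range)) range <- confident_range(params, cfg)
  r <- trace$r_mean_kohm
  conc <- suppressWarnings(invert_calibration(r, params))
  oor <- attr(conc, "out_of_range")
  conc <- as.numeric(conc)
  dc <- dc_rel <- rep(NA_real_, length(conc))
  pos <- conc > 0
  if (any(pos)) {
    bud <- concentration_uncertainty(conc[pos], params, cfg)
    y <- 1 + params$k * conc[pos]
    dc_stat <- y^(1 + params$gamma) / (params$k * params$gamma * params$rb) *
      trace$r_sem_kohm[pos]
    dc[pos] <- sqrt(bud$dc_nM^2 + dc_stat^2)
    dc_rel[pos] <- dc[pos] / conc[pos]
  }
  in_rng <- if (isTRUE(attr(range, "empty"))) rep(FALSE, length(conc)) else
    conc >= range[1] & conc <= range[2]
  out <- data.frame(
    time_s = trace$time_s, r_mean_kohm = r, r_sem_kohm = trace$r_sem_kohm,
    n = trace$n, c_nM = conc, dc_nM = dc, dc_rel = dc_rel,
    below_lod = r > limits$lod_resistance,
    below_loq = r > limits$loq_resistance,
    in_confident_range = in_rng,
    out_of_range = oor)
  class(out) <- c("ldr_trace", "data.frame")
  out
}

#' Plot a quantified time trace
#'
#' Concentration against time with the propagated uncertainty as a shaded
#' band, in the style of the reader's real-time display.
#'
#' @param x An `ldr_trace` from [quantify_timetrace()].
#' @param ... Passed to `plot`.
#' @return Invisibly, `x`.
#' @export
plot.ldr_trace <- function(x, ...) {
  t_min <- x$time_s / 60
  hi <- x$c_nM + x$dc_nM; lo <- pmax(x$c_nM - x$dc_nM, 0)
  plot(t_min, x$c_nM, type = "n",
       ylim = c(0, max(hi, na.rm = TRUE)),
       xlab = "time [min]", ylab = "concentration [nM]", ...)
  ok <- !is.na(hi)
  graphics::polygon(c(t_min[ok], rev(t_min[ok])), c(hi[ok], rev(lo[ok])),
                    col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  graphics::lines(t_min, x$c_nM, col = "steelblue4", lwd = 2)
  invisible(x)
}

#' Run the full calibration workflow
#'
#' End-to-end calibration from a dilution-series table (or CSV): relative
#' resistance, weighted fit, IUPAC limits, confident range, plus a
#' contamination check — the trailing blanks of the series must agree with
#' the leading blanks to within 3 standard deviations of the leading-blank
#' scatter, otherwise a `ldrquant_contamination` warning is raised (or an
#' error with `strict = TRUE`).
#'
#' @param series Dilution-series data frame or path to its CSV.
#' @param cfg A [detector_config()].
#' @param threshold Confident-range threshold.
#' @param strict Escalate a contamination warning to an error.
#' @param out_json Optional path: write the calibration JSON document.
#' @return An object of class `ldr_cal_report`: list with `cal` (the
#'   `ldr_cal` fit), `limits`, `range`, `contaminated` (logical) and `json`
#'   (the document written to `out_json`).
#' @export
run_calibration_workflow <- function(series, cfg = detector_config(),
                                     threshold = 0.15, strict = FALSE,
                                     out_json = NULL) {
  if (is.character(series)) series <- read_dilution_series(series)
  series <- check_series(series)
  contaminated <- FALSE
  blanks <- series[series$is_blank, , drop = FALSE]
  if ("sequence_index" %in% names(series) && nrow(blanks) >= 4L) {
    # leading = blanks acquired before the samples of their replicate
    has_rep <- "replicate" %in% names(series)
    blank_rep <- if (has_rep) blanks$replicate else rep(1L, nrow(blanks))
    leading <- unlist(lapply(split(seq_len(nrow(blanks)), blank_rep), function(i) {
      samp <- series[!series$is_blank, , drop = FALSE]
      if (has_rep) samp <- samp[samp$replicate == blank_rep[i[1]], , drop = FALSE]
      i[blanks$sequence_index[i] < min(samp$sequence_index)]
    }))
    lead <- blanks$r_mean_kohm[leading]
    trail <- blanks$r_mean_kohm[-leading]
    if (length(lead) >= 2L && length(trail) >= 1L) {
      sd_lead <- stats::sd(lead)
      if (sd_lead > 0 &&
          abs(mean(trail) - mean(lead)) > 3 * sd_lead) {
        contaminated <- TRUE
        msg <- sprintf(
          "possible contamination: trailing blanks (%.4g kOhm) deviate from leading blanks (%.4g +/- %.3g kOhm) by more than 3 sigma",
          mean(trail), mean(lead), sd_lead)
        if (strict) {
          stop(structure(class = c("ldrquant_contamination", "error",
                                   "condition"),
                         list(message = msg, call = sys.call())))
        }
        warning(structure(class = c("ldrquant_contamination", "warning",
                                    "condition"),
                          list(message = msg, call = sys.call())))
      }
    }
  }
  cal <- ldr_calibrate(series)
  limits <- detection_limits(cal$params)
  range <- confident_range(cal$params, cfg, threshold = threshold)
  json <- c(unclass(cal$params),
            list(chi2_red = cal$chi2_red, n_points = cal$n_points,
                 sigma_blank = limits$sigma,
                 lod_kohm = limits$lod_resistance,
                 loq_kohm = limits$loq_resistance,
                 lod_nM = limits$lod_concentration,
                 loq_nM = limits$loq_concentration,
                 range_nM = as.numeric(range), threshold = threshold,
                 contaminated = contaminated))
  rep <- structure(list(cal = cal, limits = limits, range = range,
                        contaminated = contaminated, json = json),
                   class = "ldr_cal_report")
  if (!is.null(out_json)) {
    jsonlite::write_json(json, out_json, auto_unbox = TRUE, digits = NA)
  }
  rep
}

#' @export
print.ldr_cal_report <- function(x, ...) {
  print(x$cal)
  print(x$limits)
  cat(sprintf("  confident range (delta_c/c <= %g%%): %s - %s nM\n",
              100 * x$json$threshold,
              signif(x$range[1], 3), signif(x$range[2], 3)))
  if (x$contaminated) cat("  WARNING: contamination check failed\n")
  invisible(x)
}
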