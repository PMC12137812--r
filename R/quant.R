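## Calibration-curve quantification and scan-time / imaging-dose accounting.

#' Fit a calibration curve from known concentrations
#'
#' Least-squares fit of reconstructed pixel intensity against known GNP
#' concentration, constrained through the origin (zero signal means zero
#' gold). The default is linear -- XRF signal is linear in concentration at
#' these levels -- with an optional quadratic-through-origin alternative.
#'
#' @param known_concentrations wt% values (>= 0, at least 2 points).
#' @param recon_intensities Matching reconstructed intensities.
#' @param degree 1 (linear, default) or 2.
#' @return A `calibration_curve`; call it via [quantify_roi()] or
#'   `predict`-style with `curve_eval()`.
#' @export
fit_calibration <- function(known_concentrations, recon_intensities,
                            degree = 1L) {
  if (length(known_concentrations) != length(recon_intensities))
    stop("length mismatch")
  if (length(known_concentrations) < 2) stop("need at least two points")
  if (any(known_concentrations < 0)) stop("concentrations must be >= 0")
  if (max(recon_intensities) - min(recon_intensities) <= 0)
    stop("degenerate identical intensities")
  X <- stats::poly(recon_intensities, degree = degree, raw = TRUE,
                   simple = TRUE)
  beta <- qr.solve(X, known_concentrations)
  structure(list(coefficients = beta, degree = degree,
                 domain = range(recon_intensities)),
            class = "calibration_curve")
}

#' Evaluate a calibration curve
#' @param curve A `calibration_curve`.
#' @param intensity Reconstructed intensity values.
#' @return Concentrations in wt%.
#' @export
curve_eval <- function(curve, intensity) {
  stopifnot(inherits(curve, "calibration_curve"))
  out <- 0
  for (d in seq_len(curve$degree))
    out <- out + unname(curve$coefficients[d]) * intensity^d
  out
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> degree %d through origin, slope %.4g wt%%/unit\n",
              x$degree, x$coefficients[1]))
  invisible(x)
}

#' Mean GNP concentration within a region of interest
#'
#' Maps each masked pixel through the calibration curve and reports the ROI
#' mean, standard deviation (0 for a single pixel) and pixel count.
#'
#' @param img A `recon_image` (or matrix).
#' @param curve A `calibration_curve` (identity mapping if NULL, for images
#'   already in wt%).
#' @param roi Logical mask with the image's shape (non-empty).
#' @param label ROI label carried into the report.
#' @return A `quant_report`: roi, mean_wtpct, sd_wtpct, n_pixels.
#' @export
quantify_roi <- function(img, curve = NULL, roi, label = "roi") {
  grid <- if (inherits(img, "recon_image")) img$grid else as.matrix(img)
  roi <- as.matrix(roi)
  if (!all(dim(roi) == dim(grid))) stop("mask shape must match the image")
  if (!any(roi)) stop("empty ROI mask")
  v <- grid[roi]
  if (!is.null(curve)) v <- curve_eval(curve, v)
  structure(list(roi = label, mean_wtpct = mean(v),
                 sd_wtpct = if (length(v) > 1) stats::sd(v) else 0,
                 n_pixels = length(v)),
            class = "quant_report")
}

#' @export
print.quant_report <- function(x, ...) {
  cat(sprintf("<quant_report> %s: %.4g +/- %.4g wt%% (n = %d px)\n",
              x$roi, x$mean_wtpct, x$sd_wtpct, x$n_pixels))
  invisible(x)
}

round_half_up <- function(x, digits = 2) floor(x * 10^digits + 0.5) / 10^digits

#' Scan time and imaging dose for a projection protocol
#'
#' `scan_time = projections * seconds_per_projection / 60` minutes and
#' `dose = scan_time * dose_rate` exactly; the benchtop dose rate at the
#' isocenter is 21.3 cGy/min. Values are kept unrounded internally;
#' `scan_time_2dp`/`dose_2dp` give the presentation values (round half up at
#' two decimals).
#'
#' @param projections Number of angular projections (>= 0).
#' @param seconds_per_projection Data acquisition time per projection (s).
#' @param dose_rate Dose rate at the isocenter in cGy/min (default 21.3).
#' @return A `dose_result`: scan_time (min), dose (cGy), their 2-decimal
#'   presentation values, and the echoed inputs.
#' @export
scan_dose <- function(projections, seconds_per_projection,
                      dose_rate = 21.3) {
  if (projections < 0 || seconds_per_projection < 0 || dose_rate < 0)
    stop("inputs must be non-negative")
  scan_time <- projections * seconds_per_projection / 60
  dose <- scan_time * dose_rate
  structure(list(scan_time = scan_time, dose = dose,
                 scan_time_2dp = round_half_up(scan_time),
                 dose_2dp = round_half_up(dose),
                 projections = projections,
                 seconds_per_projection = seconds_per_projection,
                 dose_rate = dose_rate),
            class = "dose_result")
}

#' @export
print.dose_result <- function(x, ...) {
  cat(sprintf("<dose_result> %d proj x %gs: %.2f min, %.2f cGy (%.3g cGy/min)\n",
              x$projections, x$seconds_per_projection, x$scan_time_2dp,
              x$dose_2dp, x$dose_rate))
  invisible(x)
}

#' The full scan-time / dose protocol table
#'
#' All combinations of the sparse-view ladder (30, 15, 10, 7, 5 projections)
#' with 5 s and 10 s acquisition per projection, at the benchtop dose rate.
#'
#' @param projections Projection counts (default c(30, 15, 10, 7, 5)).
#' @param seconds Acquisition times per projection (default c(5, 10)).
#' @param dose_rate Dose rate in cGy/min.
#' @return data.frame with projections, seconds, scan_time_min, dose_cGy
#'   (2-decimal presentation values).
#' @export
dose_table <- function(projections = c(30, 15, 10, 7, 5),
                       seconds = c(5, 10), dose_rate = 21.3) {
  rows <- expand.grid(seconds = seconds, projections = projections)[, 2:1]
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    d <- scan_dose(rows$projections[i], rows$seconds[i], dose_rate)
    data.frame(projections = d$projections, seconds = d$seconds_per_projection,
               scan_time_min = d$scan_time_2dp, dose_cGy = d$dose_2dp)
  }))
  rownames(out) <- NULL
  out
}
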