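## Evaluation statistics: MAE, RMSE, R-squared, Huber, SSIM, PSNR and
## Bland-Altman agreement summaries.

#' Huber loss
#'
#' `0.5 * r^2` for `|r| <= delta`, `delta * (|r| - 0.5 * delta)` otherwise;
#' quadratic near zero for smooth optimisation, linear in the tails for
#' robustness to outliers. Both branches agree at `|r| = delta`
#' (`0.5 * delta^2`).
#'
#' @param residual Numeric vector of residuals.
#' @param delta Transition point (> 0, default 1).
#' @return Mean Huber loss over the residuals.
#' @export
huber_loss <- function(residual, delta = 1) {
  if (!is.finite(delta) || delta <= 0) stop("delta must be positive")
  a <- abs(residual)
  mean(ifelse(a <= delta, 0.5 * a^2, delta * (a - 0.5 * delta)))
}

#' Regression metrics (MAE, RMSE, R-squared, Huber)
#'
#' Standard definitions with `r2 = 1 - SSres/SStot`. When the true values are
#' constant (`SStot = 0`) R-squared is undefined and reported as `NA` with
#' `r2_defined = FALSE`.
#'
#' @param y_true,y_pred Equal-length numeric vectors (n >= 2).
#' @param huber_delta Huber transition point.
#' @return A `metrics_report` list: mae, rmse, r2, huber, n, r2_defined.
#' @export
regression_metrics <- function(y_true, y_pred, huber_delta = 1) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 2) stop("need at least two samples")
  r <- y_pred - y_true
  sstot <- sum((y_true - mean(y_true))^2)
  r2 <- if (sstot > 0) 1 - sum(r^2) / sstot else NA_real_
  structure(list(mae = mean(abs(r)), rmse = sqrt(mean(r^2)), r2 = r2,
                 huber = huber_loss(r, huber_delta), n = length(y_true),
                 r2_defined = sstot > 0),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d  MAE %.4g  RMSE %.4g  R2 %s  Huber %.4g\n",
              x$n, x$mae, x$rmse,
              if (isTRUE(x$r2_defined)) sprintf("%.4f", x$r2) else "undefined",
              x$huber))
  invisible(x)
}

#' Image-pair metrics (SSIM, PSNR, RMSE, MAE)
#'
#' SSIM uses the original windowed formulation: 11 x 11 Gaussian window with
#' sigma 1.5 and stabilisation constants `C1 = (0.01 * L)^2`,
#' `C2 = (0.03 * L)^2` on the stated data range `L` (never inferred).
#' `PSNR = 10 * log10(range^2 / MSE)`, `+Inf` when the images are identical.
#'
#' @param img_true,img_pred Numeric matrices of identical shape.
#' @param data_range Dynamic range `L` of the data (> 0).
#' @return List with `ssim`, `psnr`, `rmse`, `mae`.
#' @export
image_metrics <- function(img_true, img_pred, data_range) {
  if (!all(dim(img_true) == dim(img_pred))) stop("shape mismatch")
  if (!is.finite(data_range) || data_range <= 0)
    stop("data_range must be positive")
  d <- img_pred - img_true
  mse <- mean(d^2)
  list(ssim = ssim_cpp(img_true, img_pred, data_range),
       psnr = if (mse == 0) Inf else 10 * log10(data_range^2 / mse),
       rmse = sqrt(mse), mae = mean(abs(d)))
}

#' Bland-Altman agreement summary
#'
#' Bias is the mean of `y_pred - y_true`; the limits of agreement are
#' `bias +/- 1.96` sample standard deviations of the differences.
#'
#' @param y_true,y_pred Equal-length numeric vectors (n >= 2).
#' @return A `bland_altman` list: bias, loa_low, loa_high, sd, n, and the
#'   per-pair `means`/`differences` for plotting.
#' @export
bland_altman <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 2) stop("need at least two samples")
  d <- y_pred - y_true
  s <- stats::sd(d)
  b <- mean(d)
  structure(list(bias = b, loa_low = b - 1.96 * s, loa_high = b + 1.96 * s,
                 sd = s, n = length(d),
                 means = (y_pred + y_true) / 2, differences = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.4g, LoA [%.4g, %.4g], n=%d\n",
              x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}
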