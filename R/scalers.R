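## Train-set-fitted scalers. Both carry a state checksum so downstream code
## can assert that a scaler fitted on the training split was never refitted.

scaler_checksum <- function(state) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(state, f)
  unname(tools::md5sum(f))
}

#' Fit a global z-score (standard) scaler
#'
#' Per-feature mean/sd standardisation fitted on training data only; features
#' with zero spread are given unit sd so they map to 0 instead of NaN.
#'
#' @param x Numeric matrix (samples x features) or vector.
#' @return A `zscore_scaler` with `mean`, `sd` and a state `checksum`.
#' @export
fit_zscore_scaler <- function(x) {
  x <- as.matrix(x)
  m <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  s[!is.finite(s) | s <= 0] <- 1
  st <- list(mean = m, sd = s)
  structure(c(st, list(checksum = scaler_checksum(st))),
            class = "zscore_scaler")
}

#' Apply a z-score scaler
#' @param scaler A `zscore_scaler`.
#' @param x Matrix or vector on the original scale.
#' @return Scaled data with the same shape.
#' @export
scale_transform <- function(scaler, x) UseMethod("scale_transform")

#' Invert a scaler
#' @param scaler A `zscore_scaler` or `minmax_scaler`.
#' @param x Scaled data.
#' @return Data on the original scale.
#' @export
scale_inverse <- function(scaler, x) UseMethod("scale_inverse")

#' @export
scale_transform.zscore_scaler <- function(scaler, x) {
  v <- is.null(dim(x))
  x <- as.matrix(x)
  out <- sweep(sweep(x, 2, scaler$mean), 2, scaler$sd, "/")
  if (v) drop(out) else out
}

#' @export
scale_inverse.zscore_scaler <- function(scaler, x) {
  v <- is.null(dim(x))
  x <- as.matrix(x)
  out <- sweep(sweep(x, 2, scaler$sd, "*"), 2, scaler$mean, "+")
  if (v) drop(out) else out
}

#' Fit a global min-max scaler
#'
#' Single global minimum/maximum over all supplied values (the convention for
#' sinogram/image data), mapping `[min, max]` to `[0, 1]`.
#'
#' @param x Numeric data of any shape (all values pooled).
#' @return A `minmax_scaler` with `min`, `max` and a state `checksum`.
#' @export
fit_minmax_scaler <- function(x) {
  mn <- min(x)
  mx <- max(x)
  if (!is.finite(mn) || !is.finite(mx) || mx <= mn)
    stop("min-max scaler needs max > min")
  st <- list(min = mn, max = mx)
  structure(c(st, list(checksum = scaler_checksum(st))),
            class = "minmax_scaler")
}

#' @export
scale_transform.minmax_scaler <- function(scaler, x) {
  (x - scaler$min) / (scaler$max - scaler$min)
}

#' @export
scale_inverse.minmax_scaler <- function(scaler, x) {
  x * (scaler$max - scaler$min) + scaler$min
}
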