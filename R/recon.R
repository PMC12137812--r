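## Classical reconstruction baselines: filtered back projection and ordered
## subsets expectation maximisation, both on the package's exactly adjoint
## parallel-beam projector pair.

#' A reconstructed concentration image
#'
#' @param grid 2D numeric matrix (wt% after calibration, or normalised units).
#' @param pixel_size Pixel size in mm.
#' @param method Reconstruction method tag.
#' @return An object of class `recon_image`.
#' @export
recon_image <- function(grid, pixel_size, method = "unknown") {
  grid <- as.matrix(grid)
  if (any(!is.finite(grid))) stop("reconstruction contains non-finite values")
  structure(list(grid = grid, pixel_size = pixel_size, method = method),
            class = "recon_image")
}

#' @export
print.recon_image <- function(x, ...) {
  cat(sprintf("<recon_image> %dx%d px @ %.3g mm (%s)\n",
              nrow(x$grid), ncol(x$grid), x$pixel_size, x$method))
  invisible(x)
}

ramp_filter_rows <- function(m) {
  ## Discrete Ram-Lak filtering (spatial-domain ramp response transformed to
  ## frequency space), zero-padded to avoid circular wrap-around. Projections
  ## are taken in detector-bin units.
  nt <- ncol(m)
  np <- 2^ceiling(log2(max(64, 2 * nt)))
  h <- numeric(np)
  h[1] <- 0.25
  odd <- seq(1, np / 2, by = 2)
  h[odd + 1] <- -1 / (pi * odd)^2
  h[np - odd + 1] <- -1 / (pi * odd)^2
  filt <- 2 * Re(stats::fft(h))
  out <- matrix(0, nrow(m), nt)
  for (i in seq_len(nrow(m))) {
    p <- c(m[i, ], rep(0, np - nt))
    out[i, ] <- Re(stats::fft(stats::fft(p) * filt, inverse = TRUE))[seq_len(nt)] / np
  }
  out
}

#' Filtered back projection
#'
#' Standard parallel-beam FBP on the sinogram's stated angles: Ram-Lak (ramp)
#' filtering of each projection row followed by backprojection with the
#' adjoint operator. The angular weight is `span / n_angles` (in radians,
#' halved for full 360 degree coverage, which traverses every line twice).
#'
#' The projector pair equates detector-bin spacing with pixel spacing, so
#' the natural output grid equals the number of detector bins (at
#' `translation_step` pixels); pass `grid_size` only for sinograms whose
#' bins were generated on a matching pixel grid.
#'
#' @param s A `sinogram`.
#' @param grid_size Output image side (default: the number of detector bins).
#' @param filter Currently "ramp" (Ram-Lak).
#' @return A `recon_image`.
#' @export
fbp_reconstruct <- function(s, grid_size = NULL, filter = "ramp") {
  stopifnot(inherits(s, "sinogram"))
  if (!identical(filter, "ramp")) stop("only the ramp filter is implemented")
  n <- grid_size %||% ncol(s$matrix)
  ## work in detector-bin units (the bin spacing cancels between the Radon
  ## integral and the ramp filter), then apply the pi/(2 n_angles) angular
  ## weight, halved for full 360-degree coverage (each line sampled twice)
  ## over 360 degrees every line is sampled twice, which the 1/n_angles in
  ## the angular weight already averages out -- no extra coverage factor
  q <- ramp_filter_rows(s$matrix / s$translation_step)
  na <- length(s$angles)
  img <- backproject_cpp(q, s$angles, n, 1.0) * pi / (2 * na)
  ## pixels outside the inscribed circle are not determined by a detector of
  ## the same width as the image; zero them (standard practice)
  xy <- seq_len(n) - (n + 1) / 2
  img[outer(xy^2, xy^2, "+") > (n / 2)^2] <- 0
  recon_image(img, s$translation_step, method = "fbp")
}

#' Ordered subsets expectation maximisation
#'
#' Multiplicative EM updates over angle subsets (round-robin partition):
#' `x <- x * A_s'(y_s / A_s x) / A_s' 1`. Non-negativity is preserved by
#' construction; with one subset the algorithm is MLEM and the
#' forward-projected estimate matches the data mass.
#'
#' @param s A `sinogram` with non-negative entries.
#' @param n_subsets Number of angle subsets (default 5).
#' @param n_iterations Full passes over all subsets (default 10).
#' @param grid_size Output image side (default: detector bin count).
#' @param init Initial image (default uniform positive).
#' @return A `recon_image` with an `iteration_log` attribute (data mass vs
#'   forward-projected mass per iteration).
#' @export
osem_reconstruct <- function(s, n_subsets = 5L, n_iterations = 10L,
                             grid_size = NULL, init = NULL) {
  stopifnot(inherits(s, "sinogram"))
  if (any(s$matrix < 0)) stop("OSEM requires a non-negative sinogram")
  n <- grid_size %||% ncol(s$matrix)
  na <- length(s$angles)
  n_subsets <- min(as.integer(n_subsets), na)
  subsets <- split(seq_len(na), rep_len(seq_len(n_subsets), na))
  x <- if (is.null(init)) matrix(1, n, n) else as.matrix(init)
  if (any(x < 0)) stop("init must be non-negative")
  eps <- 1e-12
  log_df <- data.frame(iteration = integer(0), data_mass = numeric(0),
                       model_mass = numeric(0))
  for (it in seq_len(n_iterations)) {
    for (sub in subsets) {
      ang <- s$angles[sub]
      fp <- radon_cpp(x, ang, ncol(s$matrix), s$translation_step)
      ratio <- s$matrix[sub, , drop = FALSE] / pmax(fp, eps)
      ratio[s$matrix[sub, , drop = FALSE] == 0 & fp <= eps] <- 0
      num <- backproject_cpp(ratio, ang, n, s$translation_step)
      den <- backproject_cpp(matrix(1, length(sub), ncol(s$matrix)), ang, n,
                             s$translation_step)
      x <- x * num / pmax(den, eps)
    }
    fp_all <- radon_cpp(x, s$angles, ncol(s$matrix), s$translation_step)
    log_df <- rbind(log_df, data.frame(iteration = it,
                                       data_mass = sum(s$matrix),
                                       model_mass = sum(fp_all)))
  }
  out <- recon_image(x, s$translation_step, method = "osem")
  attr(out, "iteration_log") <- log_df
  out
}
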