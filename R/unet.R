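#' Configuration of the sinogram-to-image U-Net
#'
#' A constant-width U-Net: the feature count stays at `base_features` through
#' every pooling level instead of doubling (sinograms do not require the
#' deep semantic capacity of natural images, and the skip connections carry
#' the low-level detail). The decoder follows the public satellite-imagery
#' U-Net family this architecture descends from: each up block is
#' BN + transpose conv (3x3, stride 2) + ReLU, skip concatenation, then
#' three BN+Conv+ReLU layers (2f -> 1.5f -> f -> f). Batch normalisation
#' precedes every convolution except the stem and output head.
#'
#' With the defaults (256 x 256 input, depth 5, 64 features, 96 post-concat
#' features) the model has exactly 1,616,289 parameters, counting the four
#' per-channel batch-norm parameters (scale, shift, moving mean/variance) as
#' deep-learning frameworks do in their totals.
#'
#' @param input_size Input side length; must be divisible by `2^depth`.
#' @param depth Number of pooling levels (default 5).
#' @param base_features Constant feature width (default 64).
#' @param post_concat_features Width of the first decoder conv after each
#'   skip concatenation (default `1.5 * base_features`).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param batch_size Minibatch size (default 128).
#' @param epochs Training epochs (default 50; no early stopping).
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(input_size = 256L, depth = 5L, base_features = 64L,
                        post_concat_features = round(1.5 * base_features),
                        learning_rate = 1e-4, batch_size = 128L,
                        epochs = 50L) {
  input_size <- as.integer(input_size)
  depth <- as.integer(depth)
  if (input_size %% 2L^depth != 0L)
    stop("input_size must be divisible by 2^depth")
  structure(list(input_size = input_size, depth = depth,
                 base_features = as.integer(base_features),
                 post_concat_features = as.integer(post_concat_features),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 loss = "mae"),
            class = "unet_config")
}

unet_cpp_cfg <- function(cfg, verbose = FALSE) {
  list(depth = cfg$depth, base_features = cfg$base_features,
       post_concat_features = cfg$post_concat_features,
       input_h = cfg$input_size, input_w = cfg$input_size,
       epochs = cfg$epochs, batch_size = cfg$batch_size,
       learning_rate = cfg$learning_rate, verbose = verbose)
}

#' Describe the U-Net and report its parameter count
#'
#' Instantiates the layer graph for the given configuration and sums the
#' parameters across all layers (convolution weights and biases plus the four
#' per-channel batch-norm parameters). The default configuration reports
#' exactly 1,616,289.
#'
#' @param cfg A `unet_config`.
#' @return A `unet_model_description`: list with `n_params`, `layers`
#'   summary and the config.
#' @export
build_unet <- function(cfg = unet_config()) {
  stopifnot(inherits(cfg, "unet_config"))
  n <- unet_param_count_cpp(cfg$depth, cfg$base_features,
                            cfg$post_concat_features, cfg$input_size,
                            cfg$input_size)
  f <- cfg$base_features
  u <- cfg$post_concat_features
  d <- cfg$depth
  layers <- data.frame(
    stage = c("stem", "encoder", "bottleneck", "decoder", "output"),
    description = c(
      sprintf("Conv3x3(1->%d)+ReLU ; BN+Conv3x3(%d->%d)+ReLU", f, f, f),
      sprintf("%d levels: pool ; [BN+Conv3x3(%d->%d)+ReLU] x2", d - 1L, f, f),
      sprintf("pool ; [BN+Conv3x3(%d->%d)+ReLU] x2", f, f),
      sprintf("%d blocks: BN+ConvT3x3/2+ReLU ; concat ; BN+Conv(%d->%d) ; BN+Conv(%d->%d) ; BN+Conv(%d->%d)",
              d, 2L * f, u, u, f, f, f),
      sprintf("Conv1x1(%d->1), linear", f)))
  structure(list(n_params = n, layers = layers, config = cfg),
            class = "unet_model_description")
}

#' @export
print.unet_model_description <- function(x, ...) {
  cat(sprintf("Constant-width U-Net (%dx%d input, depth %d, %d features)\n",
              x$config$input_size, x$config$input_size, x$config$depth,
              x$config$base_features))
  print(x$layers, row.names = FALSE)
  cat(sprintf("Parameters: %s\n", format(x$n_params, big.mark = ",")))
  invisible(x)
}

as_flat_rows <- function(x, hw) {
  ## accepts a list of matrices or an already flattened n x hw matrix
  if (is.list(x)) x <- do.call(rbind, lapply(x, as.vector))
  x <- as.matrix(x)
  if (ncol(x) != hw) stop("flattened input size mismatch")
  x
}

#' Train the sinogram-to-image U-Net
#'
#' Inputs and targets must be scaled to `[0, 1]` with a min-max scaler
#' fitted on the training split only (pass the scaler so its fingerprint can
#' be stored and checked). Optimises MAE with Adam; the history logs MAE,
#' RMSE, SSIM and PSNR per epoch on the validation split. Deterministic per
#' seed in single-threaded mode.
#'
#' @param x_train,y_train Training sinograms / target images: lists of
#'   `input_size^2` matrices or n x `input_size^2` matrices (column-major
#'   flattening), scaled to `[0, 1]`.
#' @param x_val,y_val Validation split (required).
#' @param cfg A `unet_config`.
#' @param x_scaler,y_scaler The global `minmax_scaler`s fitted on the
#'   training sinograms and training images respectively (one scaler per
#'   data stream; fitted on the training split only).
#' @param seed Integer seed.
#' @param verbose Print per-epoch progress.
#' @return A `unet_model`.
#' @export
train_unet <- function(x_train, y_train, x_val, y_val, cfg = unet_config(),
                       x_scaler = NULL, y_scaler = NULL, seed = 1L,
                       verbose = FALSE) {
  stopifnot(inherits(cfg, "unet_config"))
  hw <- cfg$input_size^2
  xt <- as_flat_rows(x_train, hw)
  yt <- as_flat_rows(y_train, hw)
  xv <- as_flat_rows(x_val, hw)
  yv <- as_flat_rows(y_val, hw)
  rng <- range(xt, yt)
  if (rng[1] < -1e-6 || rng[2] > 1 + 1e-6)
    stop("training data must be min-max scaled to [0, 1] before training")
  fit <- train_unet_cpp(xt, yt, xv, yv, unet_cpp_cfg(cfg, verbose),
                        as.integer(seed))
  structure(list(layers = fit$layers, history = fit$history,
                 n_params = fit$n_params, config = cfg,
                 x_scaler = x_scaler, y_scaler = y_scaler,
                 x_scaler_checksum = if (!is.null(x_scaler)) x_scaler$checksum,
                 y_scaler_checksum = if (!is.null(y_scaler)) y_scaler$checksum,
                 seed = as.integer(seed)),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  h <- x$history
  cat(sprintf("<unet_model> %s params, %d epochs, final val MAE %.4g, SSIM %.4f\n",
              format(x$n_params, big.mark = ","), nrow(h),
              h$val_mae[nrow(h)], h$val_ssim[nrow(h)]))
  invisible(x)
}

#' Reconstruct concentration images from sinograms
#'
#' Runs the network on `[0, 1]`-scaled sinograms, clips the linear output to
#' `[0, 1]`, and (when the model carries the training scaler) inverse
#' transforms back to the original intensity range.
#'
#' @param model A `unet_model`.
#' @param sino A single matrix, a `sinogram`, or a list/stack of them; each
#'   is resized to the network input if needed. Values must already be on
#'   the scaled `[0, 1]` range unless `scale_input = TRUE`.
#' @param scale_input Apply the model's stored sinogram min-max scaler to
#'   the input first (default TRUE when one is stored).
#' @param pixel_size Pixel size to stamp on the outputs (mm).
#' @return A `recon_image` (single input) or list of them.
#' @export
reconstruct <- function(model, sino, scale_input = !is.null(model$x_scaler),
                        pixel_size = 36 / model$config$input_size) {
  stopifnot(inherits(model, "unet_model"))
  single <- inherits(sino, "sinogram") ||
    (is.matrix(sino) && !is.list(sino))
  sinos <- if (single) list(sino) else sino
  hw <- model$config$input_size^2
  mats <- lapply(sinos, function(s) {
    m <- if (inherits(s, "sinogram")) s$matrix else as.matrix(s)
    if (!all(dim(m) == model$config$input_size))
      m <- resize_bilinear_cpp(m, model$config$input_size,
                               model$config$input_size)
    m
  })
  x <- do.call(rbind, lapply(mats, as.vector))
  if (scale_input) {
    if (is.null(model$x_scaler)) stop("model carries no sinogram scaler")
    x <- pmin(pmax(scale_transform(model$x_scaler, x), 0), 1)
  }
  if (min(x) < -1e-6 || max(x) > 1 + 1e-6)
    stop("inputs must be scaled to [0, 1] (fit/apply the min-max scaler)")
  y <- predict_unet_cpp(x, model$layers, unet_cpp_cfg(model$config))
  y <- pmin(pmax(y, 0), 1)
  out <- lapply(seq_len(nrow(y)), function(i) {
    g <- matrix(y[i, ], model$config$input_size, model$config$input_size)
    if (!is.null(model$y_scaler)) g <- scale_inverse(model$y_scaler, g)
    recon_image(g, pixel_size, method = "unet")
  })
  if (single) out[[1]] else out
}

#' Persist a trained U-Net checkpoint
#' @param model A `unet_model`.
#' @param dir Checkpoint directory.
#' @return The directory, invisibly.
#' @export
save_unet <- function(model, dir) {
  stopifnot(inherits(model, "unet_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "model.rds"))
  meta <- list(type = "unet2d", config = unclass(model$config),
               seed = model$seed, n_params = model$n_params,
               x_scaler_checksum = model$x_scaler_checksum,
               y_scaler_checksum = model$y_scaler_checksum,
               package_version = as.character(utils::packageVersion("xfct")))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Load a U-Net checkpoint saved by [save_unet()]
#' @param dir Checkpoint directory.
#' @return A `unet_model`.
#' @export
load_unet <- function(dir) {
  m <- readRDS(file.path(dir, "model.rds"))
  stopifnot(inherits(m, "unet_model"))
  m
}
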