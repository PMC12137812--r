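#' Hyperparameters of the spectral 1D CNN
#'
#' Defaults are the Bayesian-optimisation winners used throughout: two
#' convolutions (75 filters x kernel 39, then 14 x 13) with ELU activation,
#' dropout 0.22, a 260-unit dense layer, a single linear output, Adam at
#' learning rate 5.4e-5, batch 128, at most 100 epochs with early stopping
#' (patience 20, best weights restored), Huber loss. The Huber delta (1.0)
#' and the input Gaussian-noise level (0.01 in scaled units, training only)
#' are package defaults where the protocol is silent.
#'
#' @param conv1_filters,conv1_kernel First convolution width/kernel.
#' @param conv2_filters,conv2_kernel Second convolution width/kernel.
#' @param dense_units Penultimate dense width.
#' @param dropout_rate Dropout rate in `[0, 1)`.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping.
#' @param input_length Input window length (500 channels).
#' @param huber_delta Huber transition point.
#' @param input_noise_sd Gaussian-noise layer sd (scaled units, train only).
#' @return An object of class `cnn_hyperparams`.
#' @export
cnn_hyperparams <- function(conv1_filters = 75L, conv1_kernel = 39L,
                            conv2_filters = 14L, conv2_kernel = 13L,
                            dense_units = 260L, dropout_rate = 0.22,
                            learning_rate = 5.4e-5, batch_size = 128L,
                            max_epochs = 100L, early_stop_patience = 20L,
                            input_length = 500L, huber_delta = 1.0,
                            input_noise_sd = 0.01) {
  if (conv1_kernel > input_length ||
      conv2_kernel > input_length - conv1_kernel + 1L)
    stop("kernel sizes must not exceed the running input length")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (huber_delta <= 0) stop("huber_delta must be positive")
  structure(list(conv1_filters = as.integer(conv1_filters),
                 conv1_kernel = as.integer(conv1_kernel),
                 conv2_filters = as.integer(conv2_filters),
                 conv2_kernel = as.integer(conv2_kernel),
                 dense_units = as.integer(dense_units),
                 dropout_rate = dropout_rate,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 input_length = as.integer(input_length),
                 huber_delta = huber_delta,
                 input_noise_sd = input_noise_sd),
            class = "cnn_hyperparams")
}

#' Describe the 1D CNN architecture
#'
#' Returns the layer stack (input -> Gaussian noise -> conv+ELU -> conv+ELU
#' -> dropout -> flatten -> dense+ELU -> dense(1) linear) together with the
#' trainable-parameter count, without allocating any weights.
#'
#' @param h A `cnn_hyperparams`.
#' @return A `cnn_model_description`: list with `layers` (data.frame) and
#'   `n_params`.
#' @export
build_cnn <- function(h = cnn_hyperparams()) {
  stopifnot(inherits(h, "cnn_hyperparams"))
  l1 <- h$input_length - h$conv1_kernel + 1L
  l2 <- l1 - h$conv2_kernel + 1L
  flat <- l2 * h$conv2_filters
  layers <- data.frame(
    layer = c("input", "gaussian_noise", "conv1d_1", "conv1d_2", "dropout",
              "flatten", "dense", "dense_out"),
    output_shape = c(sprintf("(%d, 1)", h$input_length),
                     sprintf("(%d, 1)", h$input_length),
                     sprintf("(%d, %d)", l1, h$conv1_filters),
                     sprintf("(%d, %d)", l2, h$conv2_filters),
                     sprintf("(%d, %d)", l2, h$conv2_filters),
                     sprintf("(%d)", flat),
                     sprintf("(%d)", h$dense_units), "(1)"),
    activation = c("", "", "elu", "elu", "", "", "elu", "linear"),
    n_params = c(0L, 0L,
                 h$conv1_kernel * h$conv1_filters + h$conv1_filters,
                 h$conv2_kernel * h$conv1_filters * h$conv2_filters +
                   h$conv2_filters,
                 0L, 0L,
                 flat * h$dense_units + h$dense_units,
                 h$dense_units + 1L))
  structure(list(layers = layers, n_params = sum(layers$n_params),
                 hyperparams = h),
            class = "cnn_model_description")
}

#' @export
print.cnn_model_description <- function(x, ...) {
  cat("1D CNN spectral extractor\n")
  print(x$layers, row.names = FALSE)
  cat(sprintf("Trainable parameters: %s\n",
              format(x$n_params, big.mark = ",")))
  invisible(x)
}

#' Split spectra into train / validation / test
#'
#' First carves off `test_fraction` (floored) as the test set, then splits
#' the remaining pool by `val_fraction_of_train` (floored) into validation
#' and training. With the reference corpus of 72,800 spectra this yields
#' 50,960 / 21,840, then 40,768 / 10,192. Deterministic per seed; subsets
#' are disjoint and exhaustive.
#'
#' @param n_or_pairs Row count, or an object with rows/length (e.g.
#'   `xrf_pairs`).
#' @param test_fraction Fraction for the test set (default 0.30).
#' @param val_fraction_of_train Validation fraction of the remaining pool
#'   (default 0.20).
#' @param seed Integer seed.
#' @return List with `train`, `val`, `test` index vectors.
#' @export
split_spectra <- function(n_or_pairs, test_fraction = 0.30,
                          val_fraction_of_train = 0.20, seed = 1L) {
  n <- if (is.numeric(n_or_pairs) && length(n_or_pairs) == 1L) n_or_pairs
  else if (inherits(n_or_pairs, "xrf_pairs")) nrow(n_or_pairs$x)
  else length(n_or_pairs)
  n <- as.integer(n)
  if (n < 1L) stop("empty input")
  if (test_fraction <= 0 || test_fraction >= 1 ||
      val_fraction_of_train <= 0 || val_fraction_of_train >= 1)
    stop("fractions must lie in (0, 1)")
  set.seed(seed)
  idx <- sample.int(n)
  n_test <- floor(test_fraction * n)
  test <- idx[seq_len(n_test)]
  pool <- idx[(n_test + 1L):n]
  n_val <- floor(val_fraction_of_train * length(pool))
  list(train = sort(pool[(n_val + 1L):length(pool)]),
       val = sort(pool[seq_len(n_val)]),
       test = sort(test))
}

#' Train the spectral 1D CNN
#'
#' Z-score scalers are fitted on the training split only (inputs
#' feature-wise, targets with their own scaler) and applied unchanged to
#' validation data; training minimises the Huber loss with Adam, stops early
#' when the validation loss has not improved for `early_stop_patience`
#' epochs, and restores the weights of the best epoch. Deterministic per
#' seed in single-threaded mode.
#'
#' @param x_train,y_train Training inputs (n x 500) and netSToBg targets.
#' @param x_val,y_val Validation split (required; early stopping needs it).
#' @param h A `cnn_hyperparams`.
#' @param seed Integer experiment seed (fans out to weight init, shuffling
#'   and the noise layer).
#' @param verbose Print per-epoch progress.
#' @return A `cnn_model`: weights, scalers (+ fingerprints), history,
#'   best_epoch, hyperparams.
#' @export
train_cnn <- function(x_train, y_train, x_val, y_val,
                      h = cnn_hyperparams(), seed = 1L, verbose = FALSE) {
  stopifnot(inherits(h, "cnn_hyperparams"))
  x_train <- as.matrix(x_train)
  x_val <- as.matrix(x_val)
  if (nrow(x_val) == 0) stop("validation set must not be empty")
  if (ncol(x_train) != h$input_length)
    stop(sprintf("inputs must have %d columns", h$input_length))

  x_scaler <- fit_zscore_scaler(x_train)
  y_scaler <- fit_zscore_scaler(matrix(y_train, ncol = 1))
  xs <- scale_transform(x_scaler, x_train)
  ys <- drop(scale_transform(y_scaler, matrix(y_train, ncol = 1)))
  xvs <- scale_transform(x_scaler, x_val)
  yvs <- drop(scale_transform(y_scaler, matrix(y_val, ncol = 1)))

  hyper <- unclass(h)
  hyper$verbose <- verbose
  fit <- train_cnn1d_cpp(xs, ys, xvs, yvs, hyper, as.integer(seed))

  structure(list(weights = fit$weights, history = fit$history,
                 best_epoch = fit$best_epoch,
                 best_val_loss = fit$best_val_loss,
                 epochs_run = fit$epochs_run,
                 x_scaler = x_scaler, y_scaler = y_scaler,
                 hyperparams = h, seed = as.integer(seed)),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> trained %d epochs (best %d, val Huber %.4g)\n",
              x$epochs_run, x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' Predict net XRF signal (netSToBg) from raw spectrum windows
#'
#' Applies the model's stored input scaler, runs the network, and inverse
#' transforms predictions back to the original netSToBg scale. The scaler
#' fingerprints are verified so a refitted or foreign scaler is rejected.
#'
#' @param model A `cnn_model`.
#' @param x Spectrum windows: n x 500 matrix (raw counts), a
#'   `spectrum_set`/`xrf_pairs`, or a single `xrf_spectrum`.
#' @return Numeric vector of netSToBg predictions, one per spectrum.
#' @export
predict_net_signal <- function(model, x) {
  stopifnot(inherits(model, "cnn_model"))
  if (inherits(x, "xrf_spectrum")) x <- matrix(slice_input_window(x), 1)
  if (inherits(x, "spectrum_set"))
    x <- t(apply(x$counts, 1, slice_input_window))
  if (inherits(x, "xrf_pairs")) x <- x$x
  x <- as.matrix(x)
  if (ncol(x) != model$hyperparams$input_length)
    stop(sprintf("expected %d input channels, got %d; pass raw windows, not pre-scaled data",
                 model$hyperparams$input_length, ncol(x)))
  if (!identical(model$x_scaler$checksum,
                 scaler_checksum(list(mean = model$x_scaler$mean,
                                      sd = model$x_scaler$sd))))
    stop("input scaler state was modified after fitting")
  xs <- scale_transform(model$x_scaler, x)
  p <- predict_cnn1d_cpp(xs, model$weights, unclass(model$hyperparams))
  drop(scale_inverse(model$y_scaler, matrix(p, ncol = 1)))
}

#' Persist a trained CNN to a checkpoint directory
#'
#' Weights and scalers are written as an RDS checkpoint with a JSON metadata
#' sidecar (hyperparameters, seed, data fingerprints, package version).
#'
#' @param model A `cnn_model`.
#' @param dir Checkpoint directory (created if needed).
#' @return The directory, invisibly.
#' @export
save_cnn <- function(model, dir) {
  stopifnot(inherits(model, "cnn_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "model.rds"))
  meta <- list(type = "cnn1d", hyperparams = unclass(model$hyperparams),
               seed = model$seed, best_epoch = model$best_epoch,
               x_scaler_checksum = model$x_scaler$checksum,
               y_scaler_checksum = model$y_scaler$checksum,
               package_version = as.character(utils::packageVersion("xfct")))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Load a CNN checkpoint saved by [save_cnn()]
#' @param dir Checkpoint directory.
#' @return A `cnn_model`.
#' @export
load_cnn <- function(dir) {
  m <- readRDS(file.path(dir, "model.rds"))
  stopifnot(inherits(m, "cnn_model"))
  m
}
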