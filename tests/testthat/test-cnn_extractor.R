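test_that("hyperparameter defaults match the optimised protocol", {
  h <- cnn_hyperparams()
  expect_equal(h$conv1_filters, 75L)
  expect_equal(h$conv1_kernel, 39L)
  expect_equal(h$conv2_filters, 14L)
  expect_equal(h$conv2_kernel, 13L)
  expect_equal(h$dense_units, 260L)
  expect_equal(h$dropout_rate, 0.22)
  expect_equal(h$learning_rate, 5.4e-5)
  expect_equal(h$batch_size, 128L)
  expect_error(cnn_hyperparams(conv1_kernel = 600), "kernel")
  expect_error(cnn_hyperparams(dropout_rate = 1), "dropout")
})

test_that("model description: widths, output layer, parameter monotonicity", {
  d <- build_cnn()
  expect_equal(d$layers$output_shape[nrow(d$layers)], "(1)")
  expect_equal(d$layers$activation[nrow(d$layers)], "linear")
  expect_equal(d$layers$output_shape[7], "(260)")
  expect_equal(d$layers$output_shape[1], "(500, 1)")
  d2 <- build_cnn(cnn_hyperparams(conv1_filters = 150L))
  expect_gt(d2$n_params, d$n_params)
})

test_that("split_spectra reproduces the corpus arithmetic exactly", {
  sp <- split_spectra(72800, seed = 1)
  expect_length(sp$test, 21840L)
  expect_length(sp$val, 10192L)
  expect_length(sp$train, 40768L)
  expect_equal(length(sp$train) + length(sp$val), 50960L)
  expect_setequal(c(sp$train, sp$val, sp$test), seq_len(72800))
  sp10 <- split_spectra(10, seed = 2)
  expect_length(sp10$test, 3L)
  expect_equal(length(sp10$train) + length(sp10$val), 7L)
  expect_setequal(c(sp10$train, sp10$val, sp10$test), 1:10)
  expect_identical(split_spectra(100, seed = 5), split_spectra(100, seed = 5))
  expect_error(split_spectra(0), "empty")
})

test_that("a toy model memorises and predicts on the original scale", {
  set.seed(1)
  X <- matrix(runif(10 * 500), 10)
  y <- rowSums(X[, 1:10])
  h <- cnn_hyperparams(max_epochs = 200L, early_stop_patience = 200L,
                       batch_size = 10L, learning_rate = 2e-3,
                       dropout_rate = 0, input_noise_sd = 0)
  m <- train_cnn(X, y, X, y, h, seed = 1)
  p <- predict_net_signal(m, X)
  expect_lt(max(abs(p - y)), 0.01)
  expect_length(p, 10L)
  # determinism: identical seeds and data give identical weights
  m2 <- train_cnn(X, y, X, y, h, seed = 1)
  expect_identical(m$weights, m2$weights)
  m3 <- train_cnn(X, y, X, y, h, seed = 2)
  expect_false(identical(m$weights, m3$weights))
})

test_that("early stopping restores the best-validation weights", {
  set.seed(2)
  X <- matrix(runif(40 * 500), 40)
  y <- rnorm(40)
  h <- cnn_hyperparams(max_epochs = 60L, early_stop_patience = 5L,
                       batch_size = 20L, learning_rate = 1e-3)
  m <- train_cnn(X, y, X[1:10, ], y[1:10], h, seed = 3)
  hist <- m$history
  expect_lte(m$epochs_run, 60L)
  expect_equal(m$best_val_loss, min(hist$val_loss), tolerance = 1e-9)
  expect_equal(m$best_epoch, which.min(hist$val_loss))
  # stopping happened within patience of the best epoch
  expect_lte(m$epochs_run, m$best_epoch + 5L)
})

test_that("scalers are fitted on train only and round-trip", {
  set.seed(3)
  X <- matrix(runif(20 * 500), 20)
  sc <- fit_zscore_scaler(X)
  expect_equal(scale_inverse(sc, scale_transform(sc, X)), X,
               tolerance = 1e-12)
  y <- rnorm(20)
  scy <- fit_zscore_scaler(matrix(y, ncol = 1))
  expect_equal(drop(scale_inverse(scy, scale_transform(scy, matrix(y, ncol = 1)))),
               y, tolerance = 1e-12)
  # checksum guards against refitting/modification
  h <- cnn_hyperparams(max_epochs = 2L, batch_size = 10L)
  m <- train_cnn(X, y, X[1:5, ], y[1:5], h, seed = 1)
  m$x_scaler$mean[1] <- m$x_scaler$mean[1] + 1
  expect_error(predict_net_signal(m, X), "modified")
})

test_that("prediction rejects wrong input widths", {
  set.seed(4)
  X <- matrix(runif(12 * 500), 12)
  y <- rnorm(12)
  m <- train_cnn(X, y, X[1:4, ], y[1:4],
                 cnn_hyperparams(max_epochs = 1L, batch_size = 6L), seed = 1)
  expect_error(predict_net_signal(m, matrix(0, 3, 800)), "500")
  # spectrum containers are windowed automatically
  s <- simulate_spectrum(0.5, 10, seed = 1)
  expect_length(predict_net_signal(m, s), 1L)
})

test_that("checkpoints round-trip through save/load", {
  set.seed(5)
  X <- matrix(runif(10 * 500), 10)
  y <- rnorm(10)
  m <- train_cnn(X, y, X[1:3, ], y[1:3],
                 cnn_hyperparams(max_epochs = 1L, batch_size = 5L), seed = 1)
  d <- tempfile()
  save_cnn(m, d)
  expect_true(file.exists(file.path(d, "metadata.json")))
  m2 <- load_cnn(d)
  expect_equal(predict_net_signal(m2, X), predict_net_signal(m, X))
  unlink(d, recursive = TRUE)
})
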