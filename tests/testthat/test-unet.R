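test_that("default U-Net reports exactly 1,616,289 parameters", {
  b <- build_unet(unet_config())
  expect_identical(b$n_params, 1616289)
})

test_that("parameter count is monotone in width and valid configs enforced", {
  base <- build_unet(unet_config())$n_params
  half <- build_unet(unet_config(base_features = 32L,
                                 post_concat_features = 48L))$n_params
  expect_lt(half, base)
  expect_error(unet_config(input_size = 100, depth = 5), "divisible")
})

test_that("gradients agree with finite differences where kinks permit", {
  # float32 + ReLU/MAE kinks put a noise floor on the comparison; the check
  # asserts agreement in the aggregate, not per entry
  nn <- asNamespace("xfct")
  set.seed(3)
  cfg <- list(depth = 2L, base_features = 3L, post_concat_features = 4L,
              input_h = 16L, input_w = 16L, epochs = 1L, batch_size = 4L,
              learning_rate = 1e-3)
  X <- matrix(runif(4 * 256), 4)
  Y <- matrix(runif(4 * 256), 4)
  eps <- 1e-3
  rel <- c()
  for (ui in c(0L, 2L, 6L, 10L, 14L)) {
    g0 <- nn$unet_lossgrad_cpp(X, Y, cfg, 5L, ui, 0L, 0L, 0)
    lp <- nn$unet_lossgrad_cpp(X, Y, cfg, 5L, ui, 0L, 0L, eps)$loss
    lm <- nn$unet_lossgrad_cpp(X, Y, cfg, 5L, ui, 0L, 0L, -eps)$loss
    num <- (lp - lm) / (2 * eps)
    rel <- c(rel, abs(g0$grad - num) / max(abs(g0$grad), abs(num), 1e-3))
  }
  expect_lt(median(rel), 0.15)
})

test_that("training decreases the loss and the net memorises structure", {
  set.seed(7)
  imgs <- lapply(1:8, function(i) make_3h_phantom(runif(3, .2, 1),
                                                  grid_size = 32))
  sins <- lapply(imgs, function(p) resize_to_input(radon_project(p, 30), 32))
  scx <- fit_minmax_scaler(c(unlist(sins), 0))
  scy <- fit_minmax_scaler(c(unlist(lapply(imgs, `[[`, "grid")), 0))
  tr <- function(v, sc) lapply(v, function(m)
    pmin(pmax(scale_transform(sc, as.matrix(m)), 0), 1))
  x <- tr(sins, scx)
  y <- tr(lapply(imgs, `[[`, "grid"), scy)
  cfg <- unet_config(input_size = 32, depth = 3, base_features = 8,
                     post_concat_features = 12, batch_size = 8,
                     epochs = 60, learning_rate = 3e-3)
  m <- train_unet(x, y, x, y, cfg, x_scaler = scx, y_scaler = scy, seed = 1)
  h <- m$history
  expect_equal(nrow(h), 60L)                  # history length = epochs run
  expect_lt(h$loss[60], 0.25 * h$loss[1])    # strong one-batch overfit trend
  expect_gt(h$val_ssim[60], h$val_ssim[1])
  # reconstruction returns finite images on the original scale
  r <- reconstruct(m, sins[[1]])
  expect_true(all(is.finite(r$grid)))
  expect_equal(dim(r$grid), c(32L, 32L))
  # batch of N sinograms -> N images
  rl <- reconstruct(m, sins[1:3])
  expect_length(rl, 3L)
  # determinism
  m2 <- train_unet(x, y, x, y, cfg, x_scaler = scx, y_scaler = scy, seed = 1)
  expect_identical(m$layers, m2$layers)
})

test_that("min-max scaler round-trips and inputs are validated", {
  set.seed(8)
  v <- matrix(runif(100, -3, 7), 10)
  sc <- fit_minmax_scaler(v)
  expect_equal(scale_inverse(sc, scale_transform(sc, v)), v,
               tolerance = 1e-12)
  expect_true(all(scale_transform(sc, v) >= 0 &
                    scale_transform(sc, v) <= 1))
  expect_error(fit_minmax_scaler(rep(1, 5)), "max > min")
  # unscaled data rejected by the trainer
  cfg <- unet_config(input_size = 16, depth = 2, base_features = 4,
                     post_concat_features = 6, epochs = 1, batch_size = 2)
  bad <- lapply(1:2, function(i) matrix(5, 16, 16))
  expect_error(train_unet(bad, bad, bad, bad, cfg), "scaled")
})

test_that("untrained network maps a zero sinogram to finite output", {
  cfg <- unet_config(input_size = 16, depth = 2, base_features = 4,
                     post_concat_features = 6, epochs = 1, batch_size = 2)
  z <- lapply(1:2, function(i) matrix(0, 16, 16))
  o <- lapply(1:2, function(i) matrix(runif(256), 16))
  sc <- fit_minmax_scaler(c(0, 1))
  m <- train_unet(z, o, z, o, cfg, x_scaler = sc, y_scaler = sc, seed = 1)
  r <- reconstruct(m, matrix(0, 16, 16), scale_input = FALSE)
  expect_true(all(is.finite(r$grid)))
  expect_error(reconstruct(m, matrix(2, 16, 16), scale_input = FALSE),
               "scaled")
})

test_that("U-Net checkpoints round-trip", {
  cfg <- unet_config(input_size = 16, depth = 2, base_features = 4,
                     post_concat_features = 6, epochs = 1, batch_size = 2)
  x <- lapply(1:2, function(i) matrix(runif(256), 16))
  sc <- fit_minmax_scaler(c(0, 1))
  m <- train_unet(x, x, x, x, cfg, x_scaler = sc, y_scaler = sc, seed = 1)
  d <- tempfile()
  save_unet(m, d)
  m2 <- load_unet(d)
  r1 <- reconstruct(m, x[[1]], scale_input = FALSE)
  r2 <- reconstruct(m2, x[[1]], scale_input = FALSE)
  expect_identical(r1$grid, r2$grid)
  unlink(d, recursive = TRUE)
})
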