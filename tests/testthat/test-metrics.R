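test_that("huber loss follows its two branches and is continuous", {
  expect_equal(huber_loss(0.5, delta = 1), 0.125)
  expect_equal(huber_loss(2, delta = 1), 1.5)
  # continuity at |r| = delta: both branches give 0.5 delta^2
  for (delta in c(0.3, 1, 2.5)) {
    expect_equal(huber_loss(delta, delta), 0.5 * delta^2)
    expect_equal(huber_loss(delta + 1e-9, delta), 0.5 * delta^2,
                 tolerance = 1e-6)
  }
  expect_error(huber_loss(1, delta = 0), "positive")
})

test_that("huber limits recover MSE and MAE", {
  set.seed(1)
  r <- rnorm(200)
  expect_equal(huber_loss(r, delta = 1e6) / 0.5, mean(r^2), tolerance = 1e-9)
  expect_equal(huber_loss(r, delta = 1e-8) / 1e-8, mean(abs(r)),
               tolerance = 1e-4)
})

test_that("regression metrics match hand arithmetic", {
  m <- regression_metrics(c(0, 1, 2), c(0, 1, 3))
  expect_equal(m$mae, 1 / 3)
  expect_equal(m$rmse, sqrt(1 / 3))
  expect_equal(m$r2, 0.5)
  perfect <- regression_metrics(1:5, 1:5)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$r2, 1)
  # predicting the mean gives r2 = 0
  y <- c(1, 2, 3, 6)
  expect_equal(regression_metrics(y, rep(mean(y), 4))$r2, 0)
  # constant truth: undefined r2, flagged
  flat <- regression_metrics(rep(2, 4), c(1, 2, 3, 2))
  expect_false(flat$r2_defined)
  expect_true(is.na(flat$r2))
})

test_that("image metrics: PSNR closed form and SSIM extremes", {
  set.seed(2)
  a <- matrix(runif(32 * 32), 32)
  expect_equal(image_metrics(a, a, 1)$ssim, 1, tolerance = 1e-9)
  expect_equal(image_metrics(a, a, 1)$psnr, Inf)
  # MSE 0.01 at range 1 -> PSNR 20
  b <- a + 0.1
  expect_equal(image_metrics(a, b, 1)$psnr, 20, tolerance = 1e-9)
  # anti-correlated checkerboard
  cb <- matrix(rep_len(c(0, 1), 32 * 32), 32)
  expect_lte(image_metrics(cb, 1 - cb, 1)$ssim, 0)
  expect_error(image_metrics(a, matrix(0, 3, 3), 1), "shape")
  expect_error(image_metrics(a, a, 0), "positive")
})

test_that("PSNR strictly decreases with added noise variance", {
  set.seed(3)
  truth <- matrix(runif(48 * 48), 48)
  psnrs <- vapply(c(0.01, 0.05, 0.2), function(s)
    image_metrics(truth, truth + matrix(rnorm(48 * 48, 0, s), 48), 1)$psnr, 0)
  expect_true(all(diff(psnrs) < 0))
})

test_that("bland-altman matches hand arithmetic", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)
  ba1 <- bland_altman(rep(0, 4), rep(1, 4))
  expect_equal(ba1$bias, 1)
  expect_equal(c(ba1$loa_low, ba1$loa_high), c(1, 1))
  # differences [0, 2]: bias 1, sample sd sqrt(2)
  ba2 <- bland_altman(c(0, 0), c(0, 2))
  expect_equal(ba2$bias, 1)
  expect_equal(ba2$sd, sqrt(2))
  expect_equal(ba2$loa_low, 1 - 1.96 * sqrt(2))
  expect_equal(ba2$loa_high, 1 + 1.96 * sqrt(2))
  expect_error(bland_altman(1, 1), "two")
})

test_that("metrics are permutation-invariant over paired samples", {
  set.seed(4)
  y <- runif(50)
  p <- y + rnorm(50, 0, 0.1)
  o <- sample(50)
  m1 <- regression_metrics(y, p)
  m2 <- regression_metrics(y[o], p[o])
  expect_equal(m1$mae, m2$mae)
  expect_equal(m1$r2, m2$r2)
  b1 <- bland_altman(y, p)
  b2 <- bland_altman(y[o], p[o])
  expect_equal(b1$loa_low, b2$loa_low)
})
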