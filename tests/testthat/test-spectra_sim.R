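test_that("energy calibration maps channels to the stated energy grid", {
  cal <- energy_calibration()
  expect_equal(cal$n_channels, 800L)
  # channels 200-700 span exactly 32-112 keV
  expect_equal(cal$offset + 200 * cal$bin_width, 32)
  expect_equal(cal$offset + 700 * cal$bin_width, 112)
  expect_equal(energy_to_channel(cal, 68.804), 430L)
  expect_error(energy_to_channel(cal, 200), "outside")
  expect_error(energy_calibration(bin_width = 0), "positive")
})

test_that("zero concentration gives a continuum-only spectrum with zero truth", {
  s <- simulate_spectrum(0, 10, noise_free_params(), seed = 1)
  expect_equal(s$ground_truth_net, 0)
  expect_equal(s$ground_truth_netstobg, 0)
  cont <- simulate_spectrum(0, 10, noise_free_params(), seed = 99)
  expect_equal(s$counts, cont$counts)  # noise-free: seed-independent
})

test_that("doublet mode falls in the channel containing the K-alpha1 line", {
  p <- noise_free_params()
  with_sig <- simulate_spectrum(1, 10, p, seed = 1)$counts
  without <- simulate_spectrum(0, 10, p, seed = 1)$counts
  expect_equal(which.max(with_sig - without) - 1L,
               floor(p$ka1_energy / 0.16))  # = 430
})

test_that("generator ground truth is linear in concentration and time", {
  p <- noise_free_params()
  a <- simulate_spectrum(0.2, 10, p, seed = 3)
  b <- simulate_spectrum(0.4, 10, p, seed = 3)
  d <- simulate_spectrum(0.2, 20, p, seed = 3)
  expect_equal(b$ground_truth_net, 2 * a$ground_truth_net)
  expect_equal(d$ground_truth_net, 2 * a$ground_truth_net)
  expect_error(simulate_spectrum(-0.1, 10, p), "non-negative")
  # K-alpha outside calibrated range is rejected
  expect_error(
    simulate_spectrum(0.5, 10, spectrum_model_params(ka1_energy = 300)),
    "range")
})

test_that("simulation is deterministic per seed", {
  p <- spectrum_model_params()
  s1 <- simulate_spectrum(0.3, 10, p, seed = 7)
  s2 <- simulate_spectrum(0.3, 10, p, seed = 7)
  s3 <- simulate_spectrum(0.3, 10, p, seed = 8)
  expect_identical(s1$counts, s2$counts)
  expect_false(identical(s1$counts, s3$counts))
  set1 <- simulate_spectra(5, seed = 11)
  set2 <- simulate_spectra(5, seed = 11)
  expect_identical(set1$counts, set2$counts)
})

test_that("identity augmentation config reproduces the input exactly", {
  s <- simulate_spectrum(0.5, 10, seed = 2)
  id_cfg <- augmentation_config(baseline_shift_range = c(0, 0),
                                slope_range = c(0, 0),
                                scale_range = c(1, 1),
                                peak_shift_channels = 0L,
                                gaussian_noise_sd = 0)
  out <- augment_spectrum(s, id_cfg)
  expect_identical(out$counts, s$counts)
  expect_equal(out$ground_truth_net, s$ground_truth_net)
})

test_that("pure +1 channel shift translates the argmax", {
  s <- simulate_spectrum(1.0, 10, noise_free_params(), seed = 2)
  cfg <- augmentation_config(baseline_shift_range = c(0, 0),
                             slope_range = c(0, 0), scale_range = c(1, 1),
                             peak_shift_channels = 1L, gaussian_noise_sd = 0)
  out <- augment_spectrum(s, cfg)
  expect_equal(which.max(out$counts), which.max(s$counts) + 1L)
})

test_that("scaling multiplies the ground-truth label; counts stay non-negative", {
  s <- simulate_spectrum(0.5, 10, seed = 3)
  cfg <- augmentation_config(baseline_shift_range = c(0, 0),
                             slope_range = c(0, 0),
                             scale_range = c(1.25, 1.25),
                             peak_shift_channels = 0L, gaussian_noise_sd = 0)
  out <- augment_spectrum(s, cfg)
  expect_equal(out$ground_truth_net, 1.25 * s$ground_truth_net)
  # aggressive negative baseline: clipping keeps counts physical
  cfg2 <- augmentation_config(baseline_shift_range = c(-1e5, -1e5), seed = 4)
  out2 <- augment_spectrum(s, cfg2)
  expect_true(all(out2$counts >= 0))
})

test_that("augmentation multiplies the corpus exactly N x R", {
  set <- tiny_spectrum_set(n = 4)
  aug <- augment_spectra(set, reps = 7)
  expect_equal(nrow(aug$counts), 28L)
  expect_true(all(aug$counts >= 0))
  # piecewise determinism
  aug2 <- augment_spectra(set, reps = 7)
  expect_identical(aug$counts, aug2$counts)
})

test_that("efficiency correction divides counts and round-trips", {
  s <- simulate_spectrum(0.5, 10, seed = 5)
  expect_identical(apply_efficiency_correction(s)$counts, s$counts)
  half <- rep(0.5, 800)
  expect_equal(apply_efficiency_correction(s, half)$counts, 2 * s$counts)
  set.seed(1)
  curve <- runif(800, 0.2, 1)
  out <- apply_efficiency_correction(s, curve)
  expect_equal(out$counts * curve, s$counts, tolerance = 1e-12)
  expect_error(apply_efficiency_correction(s, rep(0, 800)), "positive")
})

test_that("spectra round-trip through delimited text", {
  set <- tiny_spectrum_set(n = 3)
  f <- tempfile(fileext = ".csv")
  write_spectra(set, f)
  back <- read_spectra(f)
  expect_equal(back$counts, set$counts, ignore_attr = TRUE)
  expect_equal(back$meta$concentration, set$meta$concentration)
  unlink(f)
})

test_that("input window slice is channels 200-699", {
  s <- simulate_spectrum(0.5, 10, seed = 6)
  w <- slice_input_window(s)
  expect_length(w, 500L)
  expect_identical(w, s$counts[201:700])
  expect_identical(slice_input_window(rep(1, 800)), rep(1, 500))
  expect_error(slice_input_window(rep(1, 700)), "800")
})
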