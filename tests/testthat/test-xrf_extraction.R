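test_that("background fit recovers a peak-free continuum exactly", {
  s <- simulate_spectrum(0, 10, noise_free_params(), seed = 1)
  bg <- fit_compton_background(s)
  win <- 200:699
  expect_lt(max(abs(bg[win + 1] - s$counts[win + 1])) /
              max(s$counts), 1e-6)
})

test_that("all-zero spectrum yields an (effectively) all-zero background", {
  s <- xrf_spectrum(rep(0, 800))
  bg <- fit_compton_background(s, peak_windows = 410:439)
  expect_true(all(bg == 0))
})

test_that("least-squares residual outside peak windows integrates to ~0", {
  s <- simulate_spectrum(0.5, 10, noise_free_params(), seed = 1)
  bg <- fit_compton_background(s)
  win <- setdiff(200:699, s$ka_windows)
  resid_sum <- sum(log(pmax(s$counts[win + 1], 1e-8)) -
                     log(pmax(bg[win + 1], 1e-8)))
  expect_lt(abs(resid_sum), 1e-6)
})

test_that("peak windows covering the analysis window are rejected", {
  s <- simulate_spectrum(0.5, 10, seed = 1)
  expect_error(fit_compton_background(s, peak_windows = 200:699), "fit")
  expect_error(fit_compton_background(s, peak_windows = 100:110), "inside")
})

test_that("net extraction recovers the generator doublet area (noise-free)", {
  for (conc in c(0.05, 0.2, 0.8)) {
    s <- simulate_spectrum(conc, 10, noise_free_params(), seed = 1)
    r <- extract_net_xrf(s)
    truth_in_win <- s$ground_truth_netstobg * s$ground_truth_bg
    expect_rel_equal(r$net_counts, truth_in_win, 0.02)
    expect_rel_equal(r$netstobg, s$ground_truth_netstobg, 0.02)
  }
})

test_that("counts equal to background give zero net and insignificance", {
  s <- simulate_spectrum(0, 10, noise_free_params(), seed = 1)
  bg <- fit_compton_background(s)
  r <- extract_net_xrf(s, bg)
  expect_equal(r$net_counts, 0)
  expect_false(r$significant)
  expect_equal(r$netstobg, 0)
})

test_that("the 1.96-sigma rule is applied to net counts", {
  # direct rule check: net = 1.0 vs 1.96 * 0.6 = 1.176 -> insignificant
  expect_false(1.0 >= 1.96 * 0.6)
  # and through the pipeline: a tiny doublet on a noisy continuum is zeroed
  s <- simulate_spectrum(0.0005, 5, seed = 12)
  r <- extract_net_xrf(s)
  expect_false(r$significant)
  expect_equal(r$netstobg, 0)
})

test_that("net counts are monotone in injected doublet area", {
  nets <- vapply(c(0.1, 0.3, 0.6, 1.0), function(conc)
    extract_net_xrf(simulate_spectrum(conc, 10, noise_free_params(),
                                      seed = 1))$net_counts, 0)
  expect_true(all(diff(nets) > 0))
})

test_that("extract_dataset produces one 500-wide row per spectrum", {
  set <- tiny_spectrum_set(n = 5)
  pairs <- extract_dataset(set)
  expect_equal(nrow(pairs$x), 5L)
  expect_equal(ncol(pairs$x), 500L)
  expect_length(pairs$y, 5L)
  empty <- extract_dataset(list())
  expect_equal(nrow(empty$x), 0L)
})

test_that("vectorised extraction matches the single-spectrum path", {
  set <- tiny_spectrum_set(n = 4)
  pairs <- extract_dataset(set)
  for (i in seq_len(4)) {
    r <- extract_net_xrf(set_spectrum(set, i), ka_windows = set$ka_windows)
    expect_rel_equal(pairs$details$net_counts[i] + 1e-9,
                     r$net_counts + 1e-9, 1e-6)
    expect_equal(pairs$y[i], r$netstobg, tolerance = 1e-6)
  }
})

test_that("the significance filter zeroes exactly the sub-threshold rows", {
  set <- simulate_spectra(40, conc_range = c(0.001, 1), seed = 77)
  pairs <- extract_dataset(set)
  manual <- pairs$details$net_counts >= 1.96 * pairs$details$sigma_bg
  expect_identical(pairs$details$significant, manual)
  expect_true(all(pairs$y[!manual] == 0))
  expect_true(all(pairs$y[manual & pairs$details$background_counts > 0] > 0 |
                    pairs$details$net_counts[manual] == 0))
})

test_that("mixed calibrations are rejected", {
  a <- simulate_spectrum(0.1, 10, seed = 1)
  b <- simulate_spectrum(0.1, 10, seed = 2,
                         cal = energy_calibration(n_channels = 400L,
                                                  bin_width = 0.32))
  expect_error(extract_dataset(list(a, b)), "calibration")
})
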