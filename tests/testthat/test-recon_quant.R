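test_that("FBP inverts the Radon transform at dense angles", {
  ph <- smooth_phantom(64)
  s <- radon_project(ph, n_angles = 180)
  fb <- fbp_reconstruct(s)
  expect_gt(image_metrics(ph$grid, fb$grid, max(ph$grid))$ssim, 0.95)
  # zero sinogram -> zero image; linearity
  z <- fbp_reconstruct(sinogram(matrix(0, 10, 32), seq(0, 324, by = 36), 1))
  expect_true(all(z$grid == 0))
  fb2 <- fbp_reconstruct(sinogram(2 * s$matrix, s$angles, s$translation_step))
  expect_equal(fb2$grid, 2 * fb$grid, tolerance = 1e-9)
})

test_that("MLEM (one subset) matches data mass and stays non-negative", {
  ph <- make_3h_phantom(grid_size = 48)
  s <- radon_project(ph, n_angles = 30)
  o <- osem_reconstruct(s, n_subsets = 1, n_iterations = 20, grid_size = 48)
  lg <- attr(o, "iteration_log")
  expect_lt(abs(lg$model_mass[20] - lg$data_mass[20]) / lg$data_mass[20],
            0.01)
  expect_true(all(o$grid >= 0))
})

test_that("OSEM: zero data zeroes the image; subsets accelerate", {
  ph <- make_3h_phantom(grid_size = 32)
  s <- radon_project(ph, n_angles = 10)
  z <- osem_reconstruct(sinogram(matrix(0, 10, 32), s$angles,
                                 s$translation_step),
                        n_subsets = 1, n_iterations = 1, grid_size = 32)
  expect_true(all(z$grid == 0))
  expect_error(osem_reconstruct(sinogram(s$matrix - 10, s$angles,
                                         s$translation_step) ),
               "non-negative")
})

test_that("FBP and OSEM agree on dense-angle noise-free phantoms", {
  ph <- make_3h_phantom(grid_size = 48)
  s <- radon_project(ph, n_angles = 120)
  fb <- fbp_reconstruct(s)
  os <- osem_reconstruct(s, n_subsets = 5, n_iterations = 10, grid_size = 48)
  expect_gt(image_metrics(fb$grid, os$grid, max(ph$grid))$ssim, 0.9)
})

test_that("calibration fit is linear through the origin", {
  cc <- fit_calibration(c(0, 1), c(0, 2))
  expect_equal(unname(cc$coefficients[1]), 0.5)
  expect_equal(curve_eval(cc, 0), 0)
  # perfect linear data -> zero residuals
  conc <- c(0, 0.3, 0.5, 1.0)
  inten <- conc * 3.3
  cc2 <- fit_calibration(conc, inten)
  expect_equal(curve_eval(cc2, inten), conc, tolerance = 1e-12)
  expect_error(fit_calibration(c(0, 1), c(2, 2)), "degenerate")
  expect_error(fit_calibration(0, 1), "two")
})

test_that("ROI quantification reports mean/sd/count correctly", {
  img <- matrix(0, 10, 10)
  img[2:4, 2:4] <- 4.9
  roi <- img > 0
  q <- quantify_roi(img, NULL, roi, label = "kidney")
  expect_equal(q$mean_wtpct, 4.9)
  expect_equal(q$sd_wtpct, 0)
  expect_equal(q$n_pixels, 9L)
  # one-pixel mask
  one <- matrix(FALSE, 10, 10); one[5, 5] <- TRUE
  expect_equal(quantify_roi(img, NULL, one)$sd_wtpct, 0)
  # two-value region {0.3, 0.5}: mean 0.4, sd by definition
  img2 <- matrix(c(0.3, 0.5), 2, 2)
  q2 <- quantify_roi(img2, NULL, matrix(TRUE, 2, 2))
  expect_equal(q2$mean_wtpct, 0.4)
  expect_equal(q2$sd_wtpct, sd(c(0.3, 0.5, 0.3, 0.5)))
  # ordering invariance comes free of the mask definition
  expect_error(quantify_roi(img, NULL, matrix(FALSE, 10, 10)), "empty")
  # calibration curve applied per pixel
  cc <- fit_calibration(c(0, 1), c(0, 2))
  expect_equal(quantify_roi(matrix(2, 3, 3), cc, matrix(TRUE, 3, 3))$mean_wtpct, 1)
})

test_that("scan_dose reproduces the protocol table exactly at 2 decimals", {
  expect_equal(scan_dose(30, 10)$scan_time_2dp, 5.00)
  expect_equal(scan_dose(30, 10)$dose_2dp, 106.50)
  expect_equal(scan_dose(5, 10)$scan_time_2dp, 0.83)
  expect_equal(scan_dose(5, 10)$dose_2dp, 17.75)
  expect_equal(scan_dose(30, 5)$dose_2dp, 53.25)
  tab <- dose_table()
  expect_equal(tab$scan_time_min,
               c(2.50, 5.00, 1.25, 2.50, 0.83, 1.67, 0.58, 1.17, 0.42, 0.83))
  expect_equal(tab$dose_cGy,
               c(53.25, 106.50, 26.63, 53.25, 17.75, 35.50, 12.43, 24.85,
                 8.88, 17.75))
  # exact internal arithmetic: dose = time * rate, unrounded
  d <- scan_dose(7, 10)
  expect_equal(d$dose, d$scan_time * 21.3)
  z <- scan_dose(0, 10)
  expect_equal(c(z$scan_time, z$dose), c(0, 0))
  expect_error(scan_dose(-1, 10), "non-negative")
})
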