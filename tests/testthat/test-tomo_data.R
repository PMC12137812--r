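test_that("3H phantom geometry: three discs at the stated concentrations", {
  ph <- make_3h_phantom(c(1.0, 0.5, 0.3), grid_size = 128)
  expect_equal(max(ph$grid), 1.0)
  expect_equal(sort(setdiff(unique(as.vector(ph$grid)), 0)),
               c(0.3, 0.5, 1.0))
  # each disc area ~ pi * 3^2 mm^2 within rasterisation tolerance
  px_area <- ph$pixel_size^2
  for (v in c(1.0, 0.5, 0.3)) {
    area <- sum(ph$grid == v) * px_area
    expect_lt(abs(area - pi * 9) / (pi * 9), 0.08)
  }
  blank <- make_3h_phantom(c(0, 0, 0), grid_size = 64)
  expect_true(all(blank$grid == 0))
  expect_error(make_3h_phantom(c(1, 1, 1), ring_radius = 14), "outside")
  expect_error(make_3h_phantom(c(1, 1, 1), ring_radius = 2), "overlap")
})

test_that("organ phantom rasterises regions reproducibly", {
  ph1 <- make_organ_phantom(grid_size = 64, seed = 3)
  ph2 <- make_organ_phantom(grid_size = 64, seed = 3)
  expect_identical(ph1$grid, ph2$grid)
  expect_equal(max(ph1$grid), 4.9)  # kidneys dominate
  empty <- make_organ_phantom(region_spec = list(), grid_size = 32)
  expect_true(all(empty$grid == 0))
  # two-kidney spec -> exactly two connected components above zero
  spec2 <- list(
    list(shape = "ellipse", cx = -5, cy = 0, rx = 2.4, ry = 1.5, angle = 0,
         concentration = 4.9),
    list(shape = "ellipse", cx = 5, cy = 0, rx = 2.4, ry = 1.5, angle = 0,
         concentration = 4.9))
  g <- make_organ_phantom(spec2, grid_size = 64)$grid > 0
  # flood-fill component count
  lab <- matrix(0L, nrow(g), ncol(g))
  ncomp <- 0L
  for (i0 in seq_len(nrow(g))) for (j0 in seq_len(ncol(g))) {
    if (!g[i0, j0] || lab[i0, j0]) next
    ncomp <- ncomp + 1L
    stack <- list(c(i0, j0))
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (p[1] < 1 || p[2] < 1 || p[1] > nrow(g) || p[2] > ncol(g)) next
      if (!g[p[1], p[2]] || lab[p[1], p[2]]) next
      lab[p[1], p[2]] <- ncomp
      stack <- c(stack, list(p + c(1, 0), p - c(1, 0),
                             p + c(0, 1), p - c(0, 1)))
    }
  }
  expect_equal(ncomp, 2L)
  bad <- list(list(shape = "ellipse", cx = 0, cy = 0, rx = 1, ry = 1,
                   angle = 0, concentration = -1))
  expect_error(make_organ_phantom(bad, grid_size = 32), "non-negative")
  # tumor-like region sets the maximum
  tum <- list(list(shape = "ellipse", cx = 0, cy = 0, rx = 3, ry = 2,
                   angle = 0, concentration = 0.4))
  expect_equal(max(make_organ_phantom(tum, grid_size = 64)$grid), 0.4)
})

test_that("radon projection conserves mass per angle and is linear", {
  ph <- make_3h_phantom(grid_size = 64)
  s <- radon_project(ph, n_angles = 30)
  mass <- sum(ph$grid) * ph$pixel_size
  expect_lt(max(abs(rowSums(s$matrix) - mass)) / mass, 0.01)
  expect_equal(s$angles[2] - s$angles[1], 12)  # 30 angles over 360
  # zero image -> zero sinogram
  z <- radon_project(phantom_image(matrix(0, 32, 32), 1), 10)
  expect_true(all(z$matrix == 0))
  # linearity radon(aX + bY) = a radon(X) + b radon(Y)
  ph2 <- smooth_phantom(64)
  sa <- radon_project(phantom_image(2 * ph$grid + 3 * ph2$grid,
                                    ph$pixel_size), 15)
  sb <- radon_project(ph, 15)
  sc <- radon_project(phantom_image(ph2$grid, ph$pixel_size), 15)
  expect_equal(sa$matrix, 2 * sb$matrix + 3 * sc$matrix, tolerance = 1e-9)
})

test_that("sinogram assembly arranges 330 values into 30 x 11 angle-major", {
  vals <- seq_len(330)
  s <- assemble_sinogram(vals)
  expect_equal(dim(s$matrix), c(30L, 11L))
  expect_equal(s$matrix[1, ], as.numeric(1:11))   # first angle block
  expect_equal(s$matrix[2, ], as.numeric(12:22))
  expect_equal(s$translation_step, 3)
  expect_error(assemble_sinogram(1:100), "330")
  z <- assemble_sinogram(rep(0, 330))
  expect_true(all(z$matrix == 0))
  # permutation round trip: inverse-shuffling the assembled matrix recovers
  # the original ordering
  set.seed(1)
  perm <- sample(330)
  sp <- assemble_sinogram(vals[perm])
  flat <- as.vector(t(sp$matrix))       # angle-major flattening
  expect_equal(flat, as.numeric(vals[perm]))
  expect_equal(flat[order(perm)], as.numeric(vals))
})

test_that("projection reduction keeps round(i n / k) rows", {
  ph <- make_3h_phantom(grid_size = 32)
  s <- radon_project(ph, n_angles = 30)
  expect_identical(reduce_projections(s, 30)$matrix, s$matrix)
  r15 <- reduce_projections(s, 15)
  expect_equal(r15$angles, seq(0, 348, by = 24))
  r7 <- reduce_projections(s, 7)
  expect_equal(r7$angles, s$angles[round((0:6) * 30 / 7) + 1])
  expect_error(reduce_projections(s, 31), "between")
})

test_that("the projection ladder yields 20 distinct settings and 5,840 pairs", {
  k <- projection_settings()
  expect_length(k, 20L)
  expect_equal(max(k), 30L)
  expect_equal(min(k), 5L)
  expect_equal(292L * length(k), 5840L)
})

test_that("pair augmentation: identity, linearity, flips and rolls", {
  ph <- make_organ_phantom(grid_size = 32, seed = 5)
  s <- radon_project(ph, n_angles = 30)
  idp <- augment_pair(s, ph, list())
  expect_identical(idp$sino$matrix, s$matrix)
  expect_identical(idp$img$grid, ph$grid)
  # scaling multiplies both members
  sc <- augment_pair(s, ph, list(scale = 2.5))
  expect_equal(sc$sino$matrix, 2.5 * s$matrix)
  expect_equal(sc$img$grid, 2.5 * ph$grid)
  # horizontal flip: sinogram rows reindexed to (180 - theta) %% 360;
  # verify against the radon transform of the flipped image
  fl <- augment_pair(s, ph, list(flip = "h"))
  direct <- radon_project(fl$img, n_angles = 30)
  expect_equal(fl$sino$matrix, direct$matrix, tolerance = 1e-9)
  fv <- augment_pair(s, ph, list(flip = "v"))
  directv <- radon_project(fv$img, n_angles = 30)
  expect_equal(fv$sino$matrix, directv$matrix, tolerance = 1e-9)
  # rotation by angular steps is an exact row roll
  ro <- augment_pair(s, ph, list(rotate_steps = 3))
  expect_equal(ro$sino$matrix[4, ], s$matrix[1, ])
  # noise applies to the sinogram only and is deterministic per seed
  nz1 <- augment_pair(s, ph, list(gaussian_noise_sd = 0.5), seed = 9)
  nz2 <- augment_pair(s, ph, list(gaussian_noise_sd = 0.5), seed = 9)
  expect_identical(nz1$sino$matrix, nz2$sino$matrix)
  expect_identical(nz1$img$grid, ph$grid)
  expect_false(identical(nz1$sino$matrix, s$matrix))
})

test_that("split_pairs applies the floor/remainder rule and partitions", {
  sp <- split_pairs(vector("list", 10), seed = 1)
  expect_equal(lengths(sp), c(train = 7L, val = 2L, test = 1L))
  expect_setequal(c(sp$train, sp$val, sp$test), 1:10)
  big <- split_pairs(vector("list", 29200), seed = 1)
  expect_equal(lengths(big), c(train = 20440L, val = 5840L, test = 2920L))
  expect_error(split_pairs(list()), "empty")
  expect_error(split_pairs(vector("list", 10), fractions = c(0.5, 0.2, 0.2)),
               "sum")
})

test_that("sinogram resize preserves constants and mass", {
  s <- radon_project(make_3h_phantom(grid_size = 48), 30)
  r <- resize_to_input(s, 64)
  expect_equal(dim(r), c(64L, 64L))
  expect_equal(attr(r, "orig_dim"), c(30L, 48L))
  cst <- resize_to_input(matrix(3.7, 20, 20), 64)
  expect_true(all(abs(cst - 3.7) < 1e-12))
  expect_rel_equal(mean(r), mean(s$matrix), 0.02)
  already <- resize_to_input(matrix(1:16, 4), 4)
  expect_equal(as.vector(already), as.numeric(1:16))
})

test_that("corpus construction follows the base x settings x factor arithmetic", {
  pairs <- make_unet_corpus(n_3h = 2, n_organ = 2, grid_size = 16,
                            projection_counts = c(10L, 5L), aug_factor = 3,
                            seed = 1)
  expect_length(pairs, 4 * 2 * 3)
  expect_true(all(vapply(pairs, function(p) nrow(p$sino$matrix), 0L) %in%
                    c(10L, 5L)))
  # first replicate is the identity reduction of the full scan
  expect_equal(pairs[[1]]$replicate, 1L)
})
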