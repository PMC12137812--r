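## Phantom images, Radon forward projection, sinogram assembly from
## per-position net-signal values, sparse-view projection reduction, paired
## augmentation and dataset splitting for the sinogram-to-image network.

#' A 2D concentration phantom
#'
#' @param grid Square numeric matrix of GNP concentration in wt% (>= 0).
#' @param pixel_size Pixel size in mm.
#' @param geometry Free-form list describing the object (diameter, features).
#' @return An object of class `phantom_image`.
#' @export
phantom_image <- function(grid, pixel_size, geometry = list()) {
  grid <- as.matrix(grid)
  if (nrow(grid) != ncol(grid)) stop("phantom grid must be square")
  if (any(grid < 0)) stop("concentrations must be non-negative")
  structure(list(grid = grid, pixel_size = pixel_size, geometry = geometry),
            class = "phantom_image")
}

#' @export
print.phantom_image <- function(x, ...) {
  cat(sprintf("<phantom_image> %dx%d px @ %.3g mm, max %.3g wt%%\n",
              nrow(x$grid), ncol(x$grid), x$pixel_size, max(x$grid)))
  invisible(x)
}

#' A sinogram (angles x translation bins)
#'
#' @param matrix Numeric matrix, one row per angle.
#' @param angles Strictly increasing angles in degrees within `[0, 360)`.
#' @param translation_step Lateral bin spacing in mm.
#' @param provenance "radon" (forward-projected image) or "spectra"
#'   (assembled from per-position net-signal values).
#' @return An object of class `sinogram`.
#' @export
sinogram <- function(matrix, angles, translation_step,
                     provenance = c("radon", "spectra")) {
  provenance <- match.arg(provenance)
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != length(angles))
    stop("one sinogram row per angle required")
  if (any(diff(angles) <= 0) || any(angles < 0) || any(angles >= 360))
    stop("angles must be strictly increasing within [0, 360)")
  if (any(!is.finite(matrix))) stop("sinogram values must be finite")
  structure(list(matrix = matrix, angles = as.numeric(angles),
                 translation_step = translation_step,
                 provenance = provenance),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d angles x %d bins, step %.3g mm, %s\n",
              nrow(x$matrix), ncol(x$matrix), x$translation_step,
              x$provenance))
  invisible(x)
}

disc_mask <- function(n, pixel_size, cx, cy, r) {
  xy <- (seq_len(n) - (n + 1) / 2) * pixel_size
  outer(xy, xy, function(y, x) (x - cx)^2 + (-y - cy)^2 <= r^2)
}

#' Three-hole cylindrical phantom
#'
#' A 30 mm acrylic disc with three 6 mm GNP-loaded holes at 120 degree
#' spacing (hole centres on a 9 mm ring). Background (acrylic and outside)
#' is 0 wt%: the matrix itself carries no gold above the detection limit.
#'
#' @param hole_concentrations Three wt% values (reference object: 1.0, 0.5,
#'   0.3).
#' @param grid_size Output grid (default 256).
#' @param pixel_size Pixel size in mm (default 36 mm field of view).
#' @param phantom_diameter,hole_diameter,ring_radius Geometry in mm.
#' @return A `phantom_image`.
#' @export
make_3h_phantom <- function(hole_concentrations = c(1.0, 0.5, 0.3),
                            grid_size = 256L,
                            pixel_size = 36 / grid_size,
                            phantom_diameter = 30, hole_diameter = 6,
                            ring_radius = 9) {
  if (length(hole_concentrations) != 3L || any(hole_concentrations < 0))
    stop("need three non-negative hole concentrations")
  if (grid_size * pixel_size < phantom_diameter)
    stop("grid does not cover the phantom diameter")
  hr <- hole_diameter / 2
  if (ring_radius + hr > phantom_diameter / 2)
    stop("holes extend outside the phantom disc")
  if (2 * ring_radius * sin(pi / 3) < hole_diameter)
    stop("holes overlap")
  grid <- matrix(0, grid_size, grid_size)
  ang <- c(90, 210, 330) * pi / 180
  for (h in 1:3) {
    mask <- disc_mask(grid_size, pixel_size,
                      ring_radius * cos(ang[h]), ring_radius * sin(ang[h]), hr)
    grid[mask] <- hole_concentrations[h]
  }
  phantom_image(grid, pixel_size,
                geometry = list(type = "3H", diameter = phantom_diameter,
                                holes = hole_concentrations))
}

#' Region specification for a synthetic multi-organ phantom
#'
#' A generic mouse-like slice: body outline, paired kidneys (4.9 wt%, the
#' renal-uptake level), liver, spleen, heart, paired lungs and a low-uptake
#' tumor (0.4 wt%). Positions and sizes are jittered per seed so repeated
#' calls emulate anatomical variability. This is a synthetic stand-in for a
#' voxelised animal atlas, not a registered anatomy.
#'
#' @param seed Integer seed.
#' @param kidney_wtpct,tumor_wtpct Concentrations of the two reference
#'   regions.
#' @return List of region descriptors (shape, centre/size in mm, angle,
#'   concentration).
#' @export
mouse_region_spec <- function(seed = 1L, kidney_wtpct = 4.9,
                              tumor_wtpct = 0.4) {
  set.seed(seed)
  j <- function(x, s) x + stats::runif(1, -s, s)
  list(
    list(shape = "ellipse", cx = j(0, 0.5), cy = j(0, 0.5), rx = j(13, 1),
         ry = j(11, 1), angle = 0, concentration = 0),          # body outline
    list(shape = "ellipse", cx = j(-5, 0.6), cy = j(-2, 0.6), rx = j(2.4, 0.3),
         ry = j(1.5, 0.2), angle = j(20, 10), concentration = kidney_wtpct),
    list(shape = "ellipse", cx = j(5, 0.6), cy = j(-2, 0.6), rx = j(2.4, 0.3),
         ry = j(1.5, 0.2), angle = j(-20, 10), concentration = kidney_wtpct),
    list(shape = "ellipse", cx = j(3, 0.6), cy = j(4, 0.6), rx = j(3.2, 0.4),
         ry = j(2.2, 0.3), angle = j(10, 10), concentration = j(1.5, 0.3)),   # liver
    list(shape = "ellipse", cx = j(-6, 0.5), cy = j(4, 0.5), rx = j(1.4, 0.2),
         ry = j(0.9, 0.15), angle = j(0, 15), concentration = j(1.0, 0.2)),   # spleen
    list(shape = "ellipse", cx = j(0, 0.5), cy = j(7, 0.5), rx = j(1.6, 0.2),
         ry = j(1.6, 0.2), angle = 0, concentration = j(0.8, 0.15)),          # heart
    list(shape = "ellipse", cx = j(-3, 0.4), cy = j(7.5, 0.4), rx = j(1.2, 0.2),
         ry = j(2.0, 0.2), angle = j(10, 8), concentration = j(0.5, 0.1)),    # lung
    list(shape = "ellipse", cx = j(3.2, 0.4), cy = j(7.5, 0.4), rx = j(1.2, 0.2),
         ry = j(2.0, 0.2), angle = j(-10, 8), concentration = j(0.5, 0.1)),   # lung
    list(shape = "ellipse", cx = j(7, 0.8), cy = j(-7, 0.8), rx = j(2.0, 0.3),
         ry = j(1.6, 0.2), angle = j(0, 20), concentration = tumor_wtpct)     # tumor
  )
}

#' Multi-region ("organ") phantom
#'
#' Rasterises a list of elliptical regions into a piecewise-constant
#' concentration map; later regions overwrite earlier ones.
#'
#' @param region_spec List of regions (see [mouse_region_spec()]); NULL draws
#'   a jittered mouse-like spec from `seed`.
#' @param grid_size Output grid size.
#' @param pixel_size Pixel size in mm.
#' @param seed Integer seed used when `region_spec` is NULL.
#' @return A `phantom_image`.
#' @export
make_organ_phantom <- function(region_spec = NULL, grid_size = 256L,
                               pixel_size = 36 / grid_size, seed = 1L) {
  if (is.null(region_spec)) region_spec <- mouse_region_spec(seed)
  grid <- matrix(0, grid_size, grid_size)
  half <- grid_size * pixel_size / 2
  xy <- (seq_len(grid_size) - (grid_size + 1) / 2) * pixel_size
  X <- matrix(xy, grid_size, grid_size, byrow = TRUE)
  Y <- -matrix(xy, grid_size, grid_size)
  for (rg in region_spec) {
    if (rg$concentration < 0) stop("region concentrations must be non-negative")
    if (abs(rg$cx) + max(rg$rx, rg$ry) > half ||
        abs(rg$cy) + max(rg$rx, rg$ry) > half)
      stop("region outside the field of view")
    th <- rg$angle * pi / 180
    xr <- (X - rg$cx) * cos(th) + (Y - rg$cy) * sin(th)
    yr <- -(X - rg$cx) * sin(th) + (Y - rg$cy) * cos(th)
    mask <- (xr / rg$rx)^2 + (yr / rg$ry)^2 <= 1
    grid[mask] <- rg$concentration
  }
  phantom_image(grid, pixel_size,
                geometry = list(type = "organ", regions = region_spec))
}

#' Radon transform of a phantom
#'
#' Parallel-beam line integrals at `n_angles` equally spaced angles over
#' `angle_range` degrees, with one detector bin per image column (bin spacing
#' = pixel size). Pixel-driven bilinear splatting; each projection row sums
#' to the image mass `sum(grid) * pixel_size` for interior objects.
#'
#' @param img A `phantom_image` (or plain matrix with `pixel_size` 1).
#' @param n_angles Number of projection angles (reference scan: 30).
#' @param angle_range Angular coverage in degrees (default 360).
#' @return A `sinogram` with provenance "radon".
#' @export
radon_project <- function(img, n_angles = 30L, angle_range = 360) {
  if (!inherits(img, "phantom_image"))
    img <- phantom_image(img, pixel_size = 1)
  if (n_angles < 1) stop("n_angles must be >= 1")
  angles <- (seq_len(n_angles) - 1L) * angle_range / n_angles
  m <- radon_cpp(img$grid, angles, ncol(img$grid), img$pixel_size)
  sinogram(m, angles, translation_step = img$pixel_size, provenance = "radon")
}

#' Assemble a sinogram from per-position net-signal values
#'
#' Arranges a flat vector of netSToBg values, ordered angle-major (all
#' translations of angle 1, then angle 2, ...), into the scan geometry: 30
#' angular positions in 12 degree steps by 11 translations at 3 mm. One
#' 330-spectrum slice therefore yields one 30 x 11 sinogram.
#'
#' @param values Numeric vector of length `n_angles * n_translations`.
#' @param n_angles Angular positions (default 30).
#' @param n_translations Translational positions (default 11).
#' @param translation_step Translation step in mm (default 3).
#' @param angle_range Angular coverage in degrees (default 360).
#' @return A `sinogram` with provenance "spectra".
#' @export
assemble_sinogram <- function(values, n_angles = 30L, n_translations = 11L,
                              translation_step = 3, angle_range = 360) {
  if (length(values) != n_angles * n_translations)
    stop(sprintf("need %d values (%d angles x %d translations), got %d",
                 n_angles * n_translations, n_angles, n_translations,
                 length(values)))
  m <- matrix(values, nrow = n_angles, ncol = n_translations, byrow = TRUE)
  angles <- (seq_len(n_angles) - 1L) * angle_range / n_angles
  sinogram(m, angles, translation_step, provenance = "spectra")
}

#' Reduce the number of angular projections
#'
#' Uniform-in-angle subsampling: keeps the `k` rows at indices
#' `round(i * n / k)`, `i = 0..k-1` (0-based), updating the angle metadata.
#'
#' @param s A `sinogram` with `n` angles.
#' @param k Target angle count, `1 <= k <= n`.
#' @return A `sinogram` with `k` rows.
#' @export
reduce_projections <- function(s, k) {
  stopifnot(inherits(s, "sinogram"))
  n <- nrow(s$matrix)
  if (k < 1 || k > n) stop("k must be between 1 and the current angle count")
  idx <- round((seq_len(k) - 1L) * n / k) + 1L
  sinogram(s$matrix[idx, , drop = FALSE], s$angles[idx], s$translation_step,
           s$provenance)
}

#' The sparse-view projection-count ladder
#'
#' Twenty unique integer projection counts uniformly spaced from 30 down
#' to 5, so that 292 base images produce 5,840 sinogram-image pairs.
#'
#' @param n_settings Number of settings (default 20).
#' @param from,to Bounds (defaults 30 and 5, inclusive).
#' @return Integer vector of projection counts.
#' @export
projection_settings <- function(n_settings = 20L, from = 30L, to = 5L) {
  k <- unique(round(seq(from, to, length.out = n_settings)))
  if (length(k) != n_settings)
    stop("requested settings do not round to distinct integers")
  as.integer(k)
}

#' Consistently augment a sinogram-image pair
#'
#' Geometric operators act on both members: flips map the image mirror to the
#' corresponding projection reindexing (horizontal flip sends angle theta to
#' (180 - theta) mod 360, vertical flip to (360 - theta) mod 360), and
#' rotation is restricted to multiples of the angular step so it is an exact
#' row roll of the sinogram. Multiplicative scaling applies to both members
#' (Radon linearity); Gaussian noise is added to the sinogram only, emulating
#' measurement noise against a clean ground-truth image.
#'
#' @param sino A `sinogram`.
#' @param img A `phantom_image`.
#' @param ops List with any of `scale` (factor), `flip` ("none", "h", "v"),
#'   `rotate_steps` (integer multiples of the angular step),
#'   `gaussian_noise_sd` (absolute, sinogram units).
#' @param seed Optional seed used only when `gaussian_noise_sd > 0`.
#' @return List with the transformed `sino` and `img`.
#' @export
augment_pair <- function(sino, img, ops = list(), seed = 1L) {
  stopifnot(inherits(sino, "sinogram"), inherits(img, "phantom_image"))
  scale <- ops$scale %||% 1
  flip <- ops$flip %||% "none"
  rot <- as.integer(ops$rotate_steps %||% 0L)
  nsd <- ops$gaussian_noise_sd %||% 0

  m <- sino$matrix
  g <- img$grid
  angles <- sino$angles
  n <- length(angles)
  step <- if (n > 1) angles[2] - angles[1] else 360

  if (!identical(flip, "none")) {
    new_angles <- switch(flip,
      h = (180 - angles) %% 360,
      v = (360 - angles) %% 360,
      stop("flip must be 'none', 'h' or 'v'"))
    ord <- match(round(angles, 9), round(sort(new_angles), 9))
    if (any(is.na(ord)))
      stop("flip does not map the angle set onto itself")
    perm <- order(new_angles)
    m <- m[perm, , drop = FALSE]
    g <- if (flip == "h") g[, rev(seq_len(ncol(g))), drop = FALSE]
         else g[rev(seq_len(nrow(g))), , drop = FALSE]
  }
  if (rot != 0L) {
    ## image rotated CCW by rot*step; projections shift: row i <- row (i-rot)
    g <- rotate_bilinear_cpp(g, rot * step)
    idx <- ((seq_len(n) - 1L - rot) %% n) + 1L
    m <- m[idx, , drop = FALSE]
  }
  m <- m * scale
  g <- g * scale
  if (nsd > 0) {
    set.seed(seed)
    m <- m + matrix(stats::rnorm(length(m), 0, nsd), nrow(m))
  }
  list(sino = sinogram(m, angles, sino$translation_step, sino$provenance),
       img = phantom_image(pmax(g, 0), img$pixel_size, img$geometry))
}

#' Split paired data 70/20/10 into train/validation/test
#'
#' Disjoint, exhaustive split by the floor/remainder rule: train and
#' validation sizes are floored, the remainder goes to test. Deterministic
#' per seed.
#'
#' @param pairs A list (or anything with `length`).
#' @param fractions Three fractions summing to 1 (default 0.7/0.2/0.1).
#' @param seed Integer seed.
#' @return List with `train`, `val`, `test` index vectors.
#' @export
split_pairs <- function(pairs, fractions = c(0.7, 0.2, 0.1), seed = 1L) {
  n <- length(pairs)
  if (n == 0) stop("empty input")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  set.seed(seed)
  idx <- sample.int(n)
  n_train <- floor(fractions[1] * n)
  n_val <- floor(fractions[2] * n)
  list(train = sort(idx[seq_len(n_train)]),
       val = sort(idx[n_train + seq_len(n_val)]),
       test = sort(idx[(n_train + n_val + 1):n]))
}

#' Resize a sinogram to the network input grid
#'
#' Deterministic bilinear interpolation on cell-centre coordinates to
#' `target x target` (stretch, not zero-fill: the network has one fixed input
#' size across all projection counts). Constants are preserved exactly and
#' the mean to interpolation accuracy. The original dimensions are kept as
#' attributes so the mapping is invertible in metadata.
#'
#' @param s A `sinogram` or plain matrix.
#' @param target Output side length (default 256).
#' @return A `target x target` matrix with attributes `orig_dim`,
#'   `orig_angles`.
#' @export
resize_to_input <- function(s, target = 256L) {
  m <- if (inherits(s, "sinogram")) s$matrix else as.matrix(s)
  if (length(m) == 0) stop("empty sinogram")
  out <- if (all(dim(m) == target)) m else resize_bilinear_cpp(m, target, target)
  attr(out, "orig_dim") <- dim(m)
  if (inherits(s, "sinogram")) attr(out, "orig_angles") <- s$angles
  out
}

#' Build the sinogram-image training corpus
#'
#' Mirrors the reference dataset construction: a mix of three-hole and
#' multi-organ phantoms, forward projected at 30 angles, reduced to each
#' projection-count setting, then expanded `aug_factor`-fold with the pair
#' augmentation operators (the first replicate is the identity). At the
#' reference scale (100 + 192 base images, 20 settings, x5) this yields
#' 5,840 and then 29,200 pairs.
#'
#' @param n_3h,n_organ Numbers of three-hole / organ phantom images.
#' @param grid_size Image grid (and sinogram resize target).
#' @param projection_counts Projection ladder (default
#'   [projection_settings()]).
#' @param aug_factor Augmentation expansion factor (default 5).
#' @param n_angles Full-scan angle count (default 30).
#' @param seed Integer seed.
#' @return List of pairs; each element has `sino` (a `sinogram`), `img`
#'   (a `phantom_image`), `n_proj`, `base_id`, `replicate`.
#' @export
make_unet_corpus <- function(n_3h = 100L, n_organ = 192L, grid_size = 256L,
                             projection_counts = projection_settings(),
                             aug_factor = 5L, n_angles = 30L, seed = 1L) {
  set.seed(seed)
  hole_sets <- matrix(stats::runif(3L * n_3h, 0.1, 1.0), ncol = 3L)
  organ_seeds <- sample.int(1e6L, n_organ)
  imgs <- c(
    lapply(seq_len(n_3h), function(i)
      make_3h_phantom(hole_sets[i, ], grid_size = grid_size)),
    lapply(seq_len(n_organ), function(i)
      make_organ_phantom(grid_size = grid_size, seed = organ_seeds[i])))
  full <- lapply(imgs, radon_project, n_angles = n_angles)

  flips <- c("none", "h", "v")
  pairs <- vector("list", length(imgs) * length(projection_counts) * aug_factor)
  n <- 0L
  for (i in seq_along(imgs)) {
    set.seed((seed + 7919L * i) %% .Machine$integer.max)
    for (k in projection_counts) {
      red <- reduce_projections(full[[i]], k)
      for (r in seq_len(aug_factor)) {
        ops <- if (r == 1L) list() else list(
          scale = stats::runif(1, 0.7, 1.3),
          flip = sample(flips, 1L),
          rotate_steps = sample(0:(n_angles - 1L), 1L),
          gaussian_noise_sd = stats::runif(1, 0, 0.01) * max(full[[i]]$matrix))
        ## rotation must stay on the reduced sinogram's own angular grid;
        ## apply flips/rotation on the full sinogram, then reduce
        p <- if (r == 1L) list(sino = red, img = imgs[[i]])
        else {
          a <- augment_pair(full[[i]], imgs[[i]], ops,
                            seed = (seed + 131L * i + r) %% .Machine$integer.max)
          list(sino = reduce_projections(a$sino, k), img = a$img)
        }
        n <- n + 1L
        pairs[[n]] <- list(sino = p$sino, img = p$img, n_proj = k,
                           base_id = i, replicate = r)
      }
    }
  }
  pairs
}
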