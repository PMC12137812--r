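## Scaled replication experiments: self-contained runs of the two learned
## components on synthetic data, used by the acceptance checks and usable
## directly for benchmarking.

#' Spectral-CNN recovery experiment
#'
#' End-to-end replication of the spectral training protocol on synthetic
#' data: simulate base spectra over 0.01--1.0 wt% at the 5/10/20/60 s
#' acquisition ladder, augment each with the five spectral operators,
#' extract conventional netSToBg targets (background fit + 1.96-sigma rule),
#' split 70/30 (then 80/20 of the training pool for validation), train the
#' optimised 1D CNN with early stopping, and score the held-out test set.
#'
#' @param n_base Number of base spectra (default 28; x200 augmentation gives
#'   5,600 -- a scaled-down analogue of the 364 x 200 = 72,800 corpus).
#' @param reps Augmentation replicates per spectrum (default 200).
#' @param h CNN hyperparameters (default: the optimised set).
#' @param seed Integer seed; all stage seeds derive from it.
#' @param verbose Print training progress.
#' @return List with `metrics` (test-set `metrics_report` against the
#'   conventional-extraction targets), `metrics_truth` (against the
#'   generator's analytic netSToBg -- the exact synthetic ground truth),
#'   `bland_altman`, `model`, `n_spectra`, `splits`, `history`.
#' @export
experiment_cnn_recovery <- function(n_base = 28L, reps = 200L,
                                    h = cnn_hyperparams(), seed = 1L,
                                    verbose = FALSE) {
  seed <- as.integer(seed)
  base <- simulate_spectra(n_base, seed = seed)
  aug <- augment_spectra(base, reps = reps,
                         cfg = augmentation_config(seed = seed + 1L))
  pairs <- extract_dataset(aug)
  sp <- split_spectra(pairs, seed = seed + 2L)
  model <- train_cnn(pairs$x[sp$train, , drop = FALSE], pairs$y[sp$train],
                     pairs$x[sp$val, , drop = FALSE], pairs$y[sp$val],
                     h = h, seed = seed + 3L, verbose = verbose)
  pred <- predict_net_signal(model, pairs$x[sp$test, , drop = FALSE])
  truth <- aug$meta$ground_truth_netstobg[sp$test]
  list(metrics = regression_metrics(pairs$y[sp$test], pred,
                                    huber_delta = h$huber_delta),
       metrics_truth = regression_metrics(truth, pred,
                                          huber_delta = h$huber_delta),
       bland_altman = bland_altman(pairs$y[sp$test], pred),
       model = model, n_spectra = nrow(aug$counts), splits = sp,
       history = model$history)
}

#' Sparse-view U-Net vs FBP experiment
#'
#' Scaled replication of the sinogram-to-image study: build a phantom
#' corpus across the sparse-view projection ladder with five-fold pair
#' augmentation, split 70/20/10, train the constant-width U-Net, and compare
#' its held-out SSIM against filtered back projection at the sparse settings
#' (10, 7, 5 projections).
#'
#' The default is a reduced instance of the full architecture (32 x 32 grid,
#' depth 3, 8 features, learning rate raised to 3e-3 for the short run)
#' trained on the three-hole family only -- the reference object of the
#' sparse-view comparison; the MAE loss needs several thousand optimiser
#' steps before sparse structures emerge, so the scaled run concentrates its
#' step budget on one family. Pass `n_organ > 0` and a larger configuration
#' to reproduce the mixed-family experiment on capable hardware.
#'
#' @param n_3h,n_organ Base phantoms per family (default 20 + 0).
#' @param grid_size Image/sinogram grid (default 32).
#' @param projection_counts Ladder (default 30/15/10/7/5).
#' @param cfg U-Net configuration for the reduced instance.
#' @param sparse_at Projection counts at which the comparison is scored.
#' @param seed Integer seed.
#' @param verbose Print training progress.
#' @return List with `comparison` (data.frame: n_proj, ssim_unet, ssim_fbp
#'   per held-out phantom), `mean_ssim_unet`, `mean_ssim_fbp`, `model`.
#' @export
experiment_unet_vs_fbp <- function(n_3h = 20L, n_organ = 0L,
                                   grid_size = 32L,
                                   projection_counts = c(30L, 15L, 10L, 7L, 5L),
                                   cfg = unet_config(input_size = grid_size,
                                                     depth = 3L,
                                                     base_features = 8L,
                                                     post_concat_features = 12L,
                                                     batch_size = 16L,
                                                     epochs = 120L,
                                                     learning_rate = 3e-3),
                                   sparse_at = c(10L, 7L, 5L), seed = 1L,
                                   verbose = FALSE) {
  seed <- as.integer(seed)
  pairs <- make_unet_corpus(n_3h = n_3h, n_organ = n_organ,
                            grid_size = grid_size,
                            projection_counts = projection_counts,
                            aug_factor = 5L, seed = seed)
  sp <- split_pairs(pairs, seed = seed + 1L)
  xs <- lapply(pairs, function(p) resize_to_input(p$sino, cfg$input_size))
  ys <- lapply(pairs, function(p) p$img$grid)
  x_scaler <- fit_minmax_scaler(c(unlist(xs[sp$train]), 0))
  y_scaler <- fit_minmax_scaler(c(unlist(ys[sp$train]), 0))
  tr <- function(v, sc) lapply(v, function(m)
    pmin(pmax(scale_transform(sc, as.matrix(m)), 0), 1))
  model <- train_unet(tr(xs[sp$train], x_scaler), tr(ys[sp$train], y_scaler),
                      tr(xs[sp$val], x_scaler), tr(ys[sp$val], y_scaler),
                      cfg = cfg, x_scaler = x_scaler, y_scaler = y_scaler,
                      seed = seed + 2L, verbose = verbose)
  test_sparse <- sp$test[vapply(pairs[sp$test],
                                function(p) p$n_proj %in% sparse_at, TRUE)]
  comparison <- do.call(rbind, lapply(test_sparse, function(i) {
    p <- pairs[[i]]
    dr <- max(p$img$grid)
    if (dr <= 0) dr <- 1
    ru <- reconstruct(model, p$sino)
    rf <- fbp_reconstruct(p$sino, grid_size = grid_size)
    data.frame(pair = i, n_proj = p$n_proj,
               ssim_unet = image_metrics(p$img$grid, ru$grid, dr)$ssim,
               ssim_fbp = image_metrics(p$img$grid, pmax(rf$grid, 0),
                                        dr)$ssim)
  }))
  list(comparison = comparison,
       mean_ssim_unet = mean(comparison$ssim_unet),
       mean_ssim_fbp = mean(comparison$ssim_fbp),
       model = model)
}
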