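## End-to-end orchestration: simulate -> extract/train -> sinogram ->
## reconstruct -> quantify -> evaluate, with a self-contained run manifest
## (seeds, data fingerprints, metrics, wall-clock per stage).

obj_fingerprint <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Configuration of an end-to-end run
#'
#' Sizes default to a smoke-scale run that completes in well under five
#' minutes on one CPU; raise them towards the reference protocol (364 base
#' spectra x 200 augmentations, 292 phantoms x 20 projection settings x 5)
#' for full-scale experiments.
#'
#' @param seed Master seed; each stage derives its own from it (and logs it).
#' @param n_base_spectra,aug_reps Spectral corpus size.
#' @param cnn Hyperparameters for the spectral CNN.
#' @param n_3h,n_organ Phantom counts for the image corpus.
#' @param grid_size Phantom grid (also the U-Net input size).
#' @param projection_counts Sparse-view ladder.
#' @param unet U-Net configuration.
#' @param train_models Train the CNN/U-Net stages (otherwise stop after
#'   dataset construction).
#' @return A `run_config`.
#' @export
run_config <- function(seed = 1L, n_base_spectra = 8L, aug_reps = 10L,
                       cnn = cnn_hyperparams(max_epochs = 3L),
                       n_3h = 6L, n_organ = 6L, grid_size = 64L,
                       projection_counts = c(30L, 15L, 10L, 7L, 5L),
                       unet = unet_config(input_size = grid_size, depth = 3L,
                                          base_features = 8L,
                                          batch_size = 8L, epochs = 2L),
                       train_models = TRUE) {
  structure(list(seed = as.integer(seed),
                 n_base_spectra = as.integer(n_base_spectra),
                 aug_reps = as.integer(aug_reps), cnn = cnn,
                 n_3h = as.integer(n_3h), n_organ = as.integer(n_organ),
                 grid_size = as.integer(grid_size),
                 projection_counts = as.integer(projection_counts),
                 unet = unet, train_models = isTRUE(train_models)),
            class = "run_config")
}

#' Run the full pipeline end to end
#'
#' Executes the stages in dependency order -- spectral simulation,
#' augmentation, conventional extraction, CNN training, phantom/sinogram
#' construction, U-Net training, per-slice inference (330 spectra -> 30 x 11
#' sinogram -> image) and classical baselines -- recording a manifest entry
#' (wall-clock, derived seed, data fingerprint, headline numbers) per stage.
#' Any stage failure halts with the failing stage named.
#'
#' @param cfg A `run_config`.
#' @return A `run_manifest`: list of stage records plus the key artifacts.
#' @export
run_end_to_end <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  manifest <- list()
  artifacts <- list()
  stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest[[name]] <<- list(stage = name,
                              seconds = proc.time()[["elapsed"]] - t0,
                              seed = cfg$seed,
                              fingerprint = obj_fingerprint(res$fingerprint %||% res),
                              info = res$info %||% NULL)
    res
  }

  spectra <- stage("simulate_spectra", function() {
    s <- simulate_spectra(cfg$n_base_spectra, seed = cfg$seed)
    list(fingerprint = s$counts, info = list(n = nrow(s$counts)), set = s)
  })$set
  aug <- stage("augment_spectra", function() {
    a <- augment_spectra(spectra, reps = cfg$aug_reps,
                         cfg = augmentation_config(seed = cfg$seed))
    list(fingerprint = a$counts, info = list(n = nrow(a$counts)), set = a)
  })$set
  pairs <- stage("extract_conventional", function() {
    p <- extract_dataset(aug)
    list(fingerprint = p$y, info = list(n = length(p$y)), pairs = p)
  })$pairs

  cnn_model <- NULL
  if (cfg$train_models) {
    cnn_model <- stage("train_cnn", function() {
      sp <- split_spectra(pairs, seed = cfg$seed + 1L)
      m <- train_cnn(pairs$x[sp$train, , drop = FALSE], pairs$y[sp$train],
                     pairs$x[sp$val, , drop = FALSE], pairs$y[sp$val],
                     h = cfg$cnn, seed = cfg$seed + 2L)
      pred <- predict_net_signal(m, pairs$x[sp$test, , drop = FALSE])
      mets <- regression_metrics(pairs$y[sp$test], pred)
      list(fingerprint = m$weights, model = m,
           info = list(best_epoch = m$best_epoch, test_r2 = mets$r2,
                       test_mae = mets$mae))
    })$model
  }

  tomo <- stage("make_sinogram_pairs", function() {
    imgs <- c(
      lapply(seq_len(cfg$n_3h), function(i) {
        set.seed(cfg$seed + 10L + i)
        make_3h_phantom(stats::runif(3, 0.2, 1), grid_size = cfg$grid_size)
      }),
      lapply(seq_len(cfg$n_organ), function(i)
        make_organ_phantom(grid_size = cfg$grid_size,
                           seed = cfg$seed + 100L + i)))
    base_sino <- lapply(imgs, radon_project, n_angles = 30L)
    pairs2 <- list()
    for (i in seq_along(imgs))
      for (k in cfg$projection_counts)
        pairs2[[length(pairs2) + 1L]] <- list(
          sino = reduce_projections(base_sino[[i]], k), img = imgs[[i]])
    list(fingerprint = lapply(pairs2, function(p) p$sino$matrix),
         info = list(n_pairs = length(pairs2)), pairs = pairs2)
  })$pairs

  unet_model <- NULL
  if (cfg$train_models) {
    unet_model <- stage("train_unet", function() {
      xs <- lapply(tomo, function(p) resize_to_input(p$sino, cfg$unet$input_size))
      ys <- lapply(tomo, function(p) p$img$grid)
      sp <- split_pairs(tomo, seed = cfg$seed + 3L)
      scx <- fit_minmax_scaler(c(unlist(xs[sp$train]), 0))
      scy <- fit_minmax_scaler(c(unlist(ys[sp$train]), 0))
      tr <- function(v, sc) lapply(v, function(m)
        pmin(pmax(scale_transform(sc, m), 0), 1))
      m <- train_unet(tr(xs[sp$train], scx), tr(ys[sp$train], scy),
                      tr(xs[sp$val], scx), tr(ys[sp$val], scy),
                      cfg = cfg$unet, x_scaler = scx, y_scaler = scy,
                      seed = cfg$seed + 4L)
      list(fingerprint = m$layers, model = m,
           info = list(val_ssim = m$history$val_ssim[nrow(m$history)]))
    })$model
  }

  slice <- NULL
  if (cfg$train_models) {
    slice <- stage("per_slice_inference", function() {
      ## one slice = 330 spectra at the scan's angular/translational grid
      ph <- make_3h_phantom(grid_size = cfg$grid_size)
      ref <- radon_project(ph, n_angles = 30L)
      small <- resize_bilinear_cpp(ref$matrix, 30L, 11L)
      conc <- pmin(pmax(small / max(small), 0), 1)   # map to 0..1 wt%
      conc_flat <- as.vector(t(conc))   # angle-major ordering
      set.seed(cfg$seed + 5L)
      seeds <- sample.int(1e6, length(conc_flat))
      specs <- matrix(0, length(conc_flat), 800L)
      for (i in seq_along(conc_flat))
        specs[i, ] <- simulate_spectrum(conc_flat[i], acquisition_time = 10,
                                        seed = seeds[i])$counts
      x <- t(apply(specs, 1, slice_input_window))
      vals <- predict_net_signal(cnn_model, x)
      sino <- assemble_sinogram(pmax(vals, 0))
      up <- resize_to_input(sino, cfg$unet$input_size)
      rec_unet <- reconstruct(unet_model, up)
      ## classical baseline at the scan's native resolution: 11 detector
      ## bins at the 3 mm translation step (the projector pair equates bin
      ## and pixel spacing)
      rec_fbp <- fbp_reconstruct(sino)
      list(fingerprint = rec_unet$grid,
           info = list(n_spectra = length(vals)),
           out = list(sino = sino, unet = rec_unet, fbp = rec_fbp))
    })$out
  }

  structure(list(stages = manifest, config = cfg,
                 artifacts = list(cnn = cnn_model, unet = unet_model,
                                  slice = slice)),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  print(timing_report(x), row.names = FALSE)
  invisible(x)
}

#' Per-stage timing table of a run manifest
#'
#' Reported, never asserted: wall-clock is hardware-dependent.
#'
#' @param manifest A `run_manifest`.
#' @return data.frame with stage, seconds and fingerprint columns.
#' @export
timing_report <- function(manifest) {
  if (!inherits(manifest, "run_manifest") || !length(manifest$stages))
    stop("incomplete manifest")
  out <- do.call(rbind, lapply(manifest$stages, function(s)
    data.frame(stage = s$stage, seconds = round(s$seconds, 3),
               fingerprint = substr(s$fingerprint, 1, 8))))
  rownames(out) <- NULL
  out
}
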