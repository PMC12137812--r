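#' Parameters of the synthetic XRF/scatter spectrum model
#'
#' The synthetic spectrum is the sum of a broad Compton-like scatter continuum
#' and the gold K-alpha emission doublet, with counting noise. The continuum
#' is a log-normal-shaped hump in energy (smooth, asymmetric, falling towards
#' high energy), `cont_amplitude * t * exp(-(log(E/cont_peak))^2 /
#' (2 * cont_logsd^2))` counts per channel. The doublet is a pair of Gaussians
#' at the K-alpha1/K-alpha2 emission energies with a 2:1 amplitude ratio; its
#' total area is `concentration * signal_per_wtpct * t` counts.
#'
#' Default emission energies are the tabulated gold values (68.804 and
#' 66.990 keV); the detector response width `peak_sigma` defaults to 0.5 keV.
#'
#' @param cont_amplitude Continuum counts per channel per second at the hump
#'   mode (default 100).
#' @param cont_peak Energy of the continuum mode in keV (default 48).
#' @param cont_logsd Log-energy width of the continuum (default 0.35).
#' @param ka1_energy,ka2_energy Gold K-alpha doublet energies in keV.
#' @param ka1_ka2_ratio Amplitude ratio K-alpha1 : K-alpha2 (default 2).
#' @param peak_sigma Gaussian peak width in keV (default 0.5).
#' @param signal_per_wtpct Net doublet counts per wt% per second
#'   (default 3000).
#' @param noise_model One of "poisson", "gaussian", "none".
#' @return An object of class `spectrum_model_params`.
#' @export
spectrum_model_params <- function(cont_amplitude = 100, cont_peak = 48,
                                  cont_logsd = 0.35,
                                  ka1_energy = 68.804, ka2_energy = 66.990,
                                  ka1_ka2_ratio = 2, peak_sigma = 0.5,
                                  signal_per_wtpct = 3000,
                                  noise_model = c("poisson", "gaussian", "none")) {
  noise_model <- match.arg(noise_model)
  if (cont_amplitude < 0 || signal_per_wtpct < 0)
    stop("amplitudes must be non-negative")
  if (ka1_energy == ka2_energy)
    stop("the two K-alpha energies must differ")
  structure(
    list(cont_amplitude = cont_amplitude, cont_peak = cont_peak,
         cont_logsd = cont_logsd, ka1_energy = ka1_energy,
         ka2_energy = ka2_energy, ka1_ka2_ratio = ka1_ka2_ratio,
         peak_sigma = peak_sigma, signal_per_wtpct = signal_per_wtpct,
         noise_model = noise_model),
    class = "spectrum_model_params"
  )
}

## Noise-free model components, evaluated at channel centres.
continuum_expected <- function(params, cal, acquisition_time) {
  E <- channel_energies(cal)
  params$cont_amplitude * acquisition_time *
    exp(-(log(E / params$cont_peak))^2 / (2 * params$cont_logsd^2))
}

doublet_shape <- function(params, cal) {
  ## Unit-area doublet sampled at channel centres (area in counts once
  ## multiplied by the net signal).
  E <- channel_energies(cal)
  w1 <- params$ka1_ka2_ratio / (params$ka1_ka2_ratio + 1)
  (w1 * stats::dnorm(E, params$ka1_energy, params$peak_sigma) +
     (1 - w1) * stats::dnorm(E, params$ka2_energy, params$peak_sigma)) *
    cal$bin_width
}

#' Default K-alpha integration windows
#'
#' Windows of +/- `half_width_sigmas` * `peak_sigma` around each K-alpha
#' centre, merged when they overlap, expressed as 0-based channel indices.
#'
#' @param params A `spectrum_model_params` (only the peak positions/width are
#'   used).
#' @param cal An `energy_calibration`.
#' @param half_width_sigmas Half-width in units of `peak_sigma` (default 3).
#' @return Sorted integer vector of 0-based channel indices.
#' @export
ka_window_channels <- function(params, cal = energy_calibration(),
                               half_width_sigmas = 3) {
  hw <- half_width_sigmas * params$peak_sigma
  ch <- integer(0)
  for (e0 in c(params$ka2_energy, params$ka1_energy)) {
    lo <- energy_to_channel(cal, e0 - hw)
    hi <- energy_to_channel(cal, e0 + hw)
    ch <- c(ch, lo:hi)
  }
  sort(unique(ch))
}

## Analytic net/background truth over a window set, with the 1.96-sigma rule
## applied against Poisson background fluctuation.
analytic_netstobg <- function(net_w, bg_w) {
  if (bg_w <= 0) return(0)
  if (net_w < 1.96 * sqrt(bg_w)) return(0)
  net_w / bg_w
}

#' Simulate one XRF/scatter spectrum
#'
#' Generates a spectrum whose expected counts are
#' `continuum(E) + concentration * signal_per_wtpct * t * doublet(E)`, applies
#' the configured counting noise, and records the noise-free ground truth:
#' the doublet area inside the K-alpha windows (`ground_truth_net`) and the
#' analytic net-to-background ratio (`ground_truth_netstobg`, zeroed by the
#' 1.96-sigma rule when the noise-free net falls below the Poisson background
#' fluctuation).
#'
#' @param concentration GNP concentration in wt% (>= 0).
#' @param acquisition_time Acquisition time in seconds (> 0).
#' @param params A `spectrum_model_params`.
#' @param seed Integer seed; the output is deterministic given the seed.
#' @param cal Energy calibration (default 800 x 0.16 keV).
#' @return An `xrf_spectrum` with ground-truth fields set.
#' @export
simulate_spectrum <- function(concentration, acquisition_time = 10,
                              params = spectrum_model_params(), seed = 1L,
                              cal = energy_calibration()) {
  if (!is.finite(concentration) || concentration < 0)
    stop("concentration must be non-negative")
  if (acquisition_time <= 0) stop("acquisition_time must be positive")
  e_max <- cal$offset + cal$n_channels * cal$bin_width
  if (params$ka1_energy >= e_max || params$ka2_energy <= cal$offset)
    stop("K-alpha energies must fall inside the calibrated range")

  cont <- continuum_expected(params, cal, acquisition_time)
  area <- concentration * params$signal_per_wtpct * acquisition_time
  shape <- doublet_shape(params, cal)
  expected <- cont + area * shape

  set.seed(seed)
  counts <- switch(params$noise_model,
    poisson = as.numeric(stats::rpois(length(expected), expected)),
    gaussian = pmax(expected + stats::rnorm(length(expected),
                                            sd = sqrt(pmax(expected, 0))), 0),
    none = expected)

  win <- ka_window_channels(params, cal)
  net_w <- area * sum(shape[win + 1L])
  bg_w <- sum(cont[win + 1L])

  s <- xrf_spectrum(counts, cal, acquisition_time,
                    concentration = concentration,
                    ground_truth_net = area,
                    ground_truth_netstobg = analytic_netstobg(net_w, bg_w),
                    source = "simulated")
  s$ground_truth_bg <- bg_w
  s$ka_windows <- win
  s
}

#' Simulate a set of spectra over the benchtop acquisition conditions
#'
#' Emulates the measured training corpus: GNP concentrations log-uniform over
#' `conc_range` with a `blank_fraction` share of GNP-free baseline spectra,
#' acquisition times drawn from `times` (the 5/10/20/60 s noise ladder).
#'
#' @param n Number of spectra.
#' @param conc_range Concentration range in wt% (default 0.01--1.0).
#' @param times Candidate acquisition times in seconds.
#' @param blank_fraction Fraction of zero-concentration spectra (default 0.15).
#' @param params A `spectrum_model_params`.
#' @param seed Integer seed.
#' @param cal Energy calibration.
#' @return A `spectrum_set`.
#' @export
simulate_spectra <- function(n, conc_range = c(0.01, 1.0),
                             times = c(5, 10, 20, 60),
                             blank_fraction = 0.15,
                             params = spectrum_model_params(), seed = 1L,
                             cal = energy_calibration()) {
  stopifnot(n >= 1)
  set.seed(seed)
  conc <- exp(stats::runif(n, log(conc_range[1]), log(conc_range[2])))
  conc[stats::runif(n) < blank_fraction] <- 0
  tt <- sample(times, n, replace = TRUE)
  seeds <- sample.int(.Machine$integer.max - 1L, n)

  counts <- matrix(0, n, cal$n_channels)
  meta <- data.frame(id = seq_len(n), acquisition_time = tt,
                     concentration = conc,
                     ground_truth_net = 0, ground_truth_netstobg = 0,
                     ground_truth_bg = 0, source = "simulated")
  for (i in seq_len(n)) {
    s <- simulate_spectrum(conc[i], tt[i], params, seed = seeds[i], cal = cal)
    counts[i, ] <- s$counts
    meta$ground_truth_net[i] <- s$ground_truth_net
    meta$ground_truth_netstobg[i] <- s$ground_truth_netstobg
    meta$ground_truth_bg[i] <- s$ground_truth_bg
  }
  out <- spectrum_set(counts, meta, cal)
  out$ka_windows <- ka_window_channels(params, cal)
  out
}

#' Configuration of the five spectral augmentation operators
#'
#' The operators are: baseline shift (random vertical offset), slope shift
#' (small intensity gradient along the energy axis), multi-shift scaling
#' (random multiplicative gain), random peak shift (+/- 1 channel along the
#' energy axis) and Gaussian noise. Magnitude defaults are package choices
#' (the magnitudes are not prescribed anywhere authoritative); they are sized
#' for spectra with a few hundred counts per channel.
#'
#' @param baseline_shift_range Additive offset range in counts.
#' @param slope_range Gradient range in counts per channel.
#' @param scale_range Multiplicative factor range (strictly positive).
#' @param peak_shift_channels Integer set of admissible channel shifts.
#' @param gaussian_noise_sd Gaussian noise standard deviation in counts.
#' @param seed Integer seed.
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(baseline_shift_range = c(-20, 20),
                                slope_range = c(-0.05, 0.05),
                                scale_range = c(0.9, 1.1),
                                peak_shift_channels = -1:1,
                                gaussian_noise_sd = 10,
                                seed = 1L) {
  if (any(scale_range <= 0)) stop("scale_range must be strictly positive")
  if (gaussian_noise_sd < 0) stop("gaussian_noise_sd must be non-negative")
  peak_shift_channels <- as.integer(peak_shift_channels)
  structure(
    list(baseline_shift_range = baseline_shift_range,
         slope_range = slope_range, scale_range = scale_range,
         peak_shift_channels = peak_shift_channels,
         gaussian_noise_sd = gaussian_noise_sd, seed = as.integer(seed)),
    class = "augmentation_config"
  )
}

## Core augmentation transform on a counts vector; returns the vector and the
## drawn operator values so labels can be propagated analytically.
apply_augmentation <- function(counts, draws) {
  n <- length(counts)
  k <- draws$shift
  shifted <- if (k == 0L) counts
  else if (k > 0L) c(rep(counts[1], k), counts[seq_len(n - k)])
  else c(counts[(1 - k):n], rep(counts[n], -k))
  out <- draws$scale * shifted + draws$baseline +
    draws$slope * (seq_len(n) - 1L) + draws$noise
  pmax(out, 0)
}

draw_augmentation <- function(cfg, n_channels) {
  list(baseline = stats::runif(1, cfg$baseline_shift_range[1],
                               cfg$baseline_shift_range[2]),
       slope = stats::runif(1, cfg$slope_range[1], cfg$slope_range[2]),
       scale = stats::runif(1, cfg$scale_range[1], cfg$scale_range[2]),
       shift = sample(cfg$peak_shift_channels, 1L),
       noise = if (cfg$gaussian_noise_sd > 0)
         stats::rnorm(n_channels, 0, cfg$gaussian_noise_sd) else 0)
}

#' Augment a single spectrum
#'
#' Applies `clip0(scale * shift_k(counts) + baseline + slope * channel +
#' gaussian_noise)`. The ground-truth net signal is multiplied by the drawn
#' scale factor (gain rescales true signal); baseline, slope, shift and noise
#' perturb only the background/calibration and leave it unchanged. The
#' analytic net-to-background ratio is re-derived from the transformed net and
#' background. Deterministic given `cfg$seed`.
#'
#' @param s An `xrf_spectrum`.
#' @param cfg An `augmentation_config`.
#' @return The augmented `xrf_spectrum` (source = "augmented").
#' @export
augment_spectrum <- function(s, cfg = augmentation_config()) {
  stopifnot(inherits(s, "xrf_spectrum"), inherits(cfg, "augmentation_config"))
  set.seed(cfg$seed)
  draws <- draw_augmentation(cfg, s$calibration$n_channels)
  out <- s
  out$counts <- apply_augmentation(s$counts, draws)
  out$source <- "augmented"
  if (!is.na(s$ground_truth_net)) {
    net_w <- draws$scale * s$ground_truth_net
    out$ground_truth_net <- net_w
    if (!is.null(s$ground_truth_bg) && !is.null(s$ka_windows)) {
      win <- s$ka_windows + draws$shift
      bg_w <- draws$scale * s$ground_truth_bg +
        draws$baseline * length(win) + draws$slope * sum(win)
      out$ground_truth_bg <- bg_w
      out$ka_windows <- win
      win_area <- if (!is.na(s$ground_truth_netstobg) &&
                      s$ground_truth_netstobg > 0 && s$ground_truth_bg > 0)
        s$ground_truth_netstobg * s$ground_truth_bg / s$ground_truth_net
      else NA_real_
      net_in_win <- if (is.na(win_area)) net_w else net_w * win_area
      out$ground_truth_netstobg <- analytic_netstobg(net_in_win, bg_w)
    }
  }
  out
}

#' Augment every spectrum in a set `reps` times
#'
#' Produces exactly `nrow * reps` spectra. Randomness is derived piecewise:
#' the draw for (spectrum i, replicate j) depends only on
#' (`cfg$seed`, i, j), so any subset is reproducible.
#'
#' @param set A `spectrum_set`.
#' @param reps Replicates per spectrum (the reference protocol uses 200).
#' @param cfg An `augmentation_config`.
#' @return A `spectrum_set` with `nrow(set$counts) * reps` rows.
#' @export
augment_spectra <- function(set, reps = 200L, cfg = augmentation_config()) {
  stopifnot(inherits(set, "spectrum_set"), reps >= 1)
  n <- nrow(set$counts)
  nc <- ncol(set$counts)
  reps <- as.integer(reps)
  out_counts <- matrix(0, n * reps, nc)
  meta <- set$meta[rep(seq_len(n), each = reps), , drop = FALSE]
  meta$source <- "augmented"
  meta$base_id <- meta$id
  meta$replicate <- rep(seq_len(reps), n)
  meta$id <- seq_len(n * reps)
  rownames(meta) <- NULL

  has_bg <- !is.null(set$meta$ground_truth_bg) && !is.null(set$ka_windows)
  ch_idx <- seq_len(nc) - 1L

  for (i in seq_len(n)) {
    ## per-spectrum seed; draws laid out by replicate so (seed, i, j) pins
    ## every value
    set.seed((cfg$seed + 97003L * i) %% .Machine$integer.max)
    baseline <- stats::runif(reps, cfg$baseline_shift_range[1],
                             cfg$baseline_shift_range[2])
    slope <- stats::runif(reps, cfg$slope_range[1], cfg$slope_range[2])
    scl <- stats::runif(reps, cfg$scale_range[1], cfg$scale_range[2])
    shift <- sample(cfg$peak_shift_channels, reps, replace = TRUE)
    noise <- if (cfg$gaussian_noise_sd > 0)
      matrix(stats::rnorm(reps * nc, 0, cfg$gaussian_noise_sd), reps, nc)
    else matrix(0, reps, nc)

    x <- set$counts[i, ]
    rows <- (i - 1L) * reps + seq_len(reps)
    ## channel-shifted copies, edge-padded
    for (j in seq_len(reps)) {
      k <- shift[j]
      shifted <- if (k == 0L) x
      else if (k > 0L) c(rep(x[1], k), x[seq_len(nc - k)])
      else c(x[(1 - k):nc], rep(x[nc], -k))
      out_counts[rows[j], ] <- pmax(
        scl[j] * shifted + baseline[j] + slope[j] * ch_idx + noise[j, ], 0)
    }

    meta$ground_truth_net[rows] <- scl * set$meta$ground_truth_net[i]
    if (has_bg) {
      win <- set$ka_windows
      nw <- length(win)
      sum_win <- sum(win)
      bg0 <- set$meta$ground_truth_bg[i]
      net0 <- set$meta$ground_truth_net[i]
      r0 <- set$meta$ground_truth_netstobg[i]
      win_area <- if (!is.na(r0) && r0 > 0 && bg0 > 0 && net0 > 0)
        r0 * bg0 / net0 else 0.9973  # +/-3 sigma coverage fallback
      bg_new <- scl * bg0 + baseline * nw + slope * (sum_win + shift * nw)
      net_new <- scl * net0 * win_area
      meta$ground_truth_bg[rows] <- bg_new
      meta$ground_truth_netstobg[rows] <- ifelse(
        bg_new > 0 & net_new >= 1.96 * sqrt(pmax(bg_new, 0)),
        net_new / pmax(bg_new, 1e-12), 0)
    }
  }
  out <- spectrum_set(out_counts, meta, set$calibration)
  out$ka_windows <- set$ka_windows
  out
}
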