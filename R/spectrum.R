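#' Energy calibration of an energy-dispersive detector
#'
#' Maps detector channels to photon energy. Channel `c` (0-based) spans the
#' half-open interval `[offset + c * bin_width, offset + (c + 1) * bin_width)`
#' keV. The default calibration is the benchtop CdTe geometry used throughout
#' the package: 800 channels of 0.16 keV starting at 0 keV, so that channels
#' 200--700 span exactly 32--112 keV.
#'
#' @param n_channels Number of channels (default 800).
#' @param bin_width Channel width in keV (default 0.16).
#' @param offset Lower edge of channel 0 in keV (default 0).
#' @return An object of class `energy_calibration`.
#' @export
energy_calibration <- function(n_channels = 800L, bin_width = 0.16, offset = 0) {
  n_channels <- as.integer(n_channels)
  if (is.na(n_channels) || n_channels <= 0L)
    stop("n_channels must be a positive integer")
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("bin_width must be positive")
  structure(
    list(n_channels = n_channels, bin_width = bin_width, offset = offset),
    class = "energy_calibration"
  )
}

#' @export
print.energy_calibration <- function(x, ...) {
  cat(sprintf("<energy_calibration> %d channels x %.3g keV, offset %.3g keV [%.4g, %.4g) keV\n",
              x$n_channels, x$bin_width, x$offset,
              x$offset, x$offset + x$n_channels * x$bin_width))
  invisible(x)
}

#' Channel centre energies for a calibration
#'
#' @param cal An `energy_calibration`.
#' @return Numeric vector of length `n_channels` with bin-centre energies (keV).
#' @export
channel_energies <- function(cal) {
  stopifnot(inherits(cal, "energy_calibration"))
  cal$offset + (seq_len(cal$n_channels) - 0.5) * cal$bin_width
}

#' Map an energy to its (0-based) channel index
#'
#' @param cal An `energy_calibration`.
#' @param energy Energy in keV.
#' @return Integer 0-based channel index (floor((E - offset)/bin_width)).
#' @export
energy_to_channel <- function(cal, energy) {
  stopifnot(inherits(cal, "energy_calibration"))
  ch <- as.integer(floor((energy - cal$offset) / cal$bin_width))
  if (any(ch < 0L | ch >= cal$n_channels))
    stop("energy outside the calibrated range")
  ch
}

#' A single XRF/scatter photon spectrum
#'
#' Container for one energy-binned photon spectrum: per-channel counts,
#' the energy calibration, the acquisition time and optional labels. When the
#' spectrum originates from the synthetic generator, `ground_truth_net` holds
#' the noise-free gold K-alpha doublet area (counts) and
#' `ground_truth_netstobg` the analytic net-to-background ratio.
#'
#' @param counts Non-negative numeric vector, one value per channel.
#' @param calibration An `energy_calibration`; its `n_channels` must match
#'   `length(counts)`.
#' @param acquisition_time Acquisition time in seconds (> 0).
#' @param concentration Optional GNP concentration label in wt%.
#' @param ground_truth_net Optional noise-free net doublet area (counts).
#' @param ground_truth_netstobg Optional analytic net/background ratio.
#' @param source One of "simulated", "augmented", "file".
#' @return An object of class `xrf_spectrum`.
#' @export
xrf_spectrum <- function(counts, calibration = energy_calibration(),
                         acquisition_time = 10,
                         concentration = NA_real_,
                         ground_truth_net = NA_real_,
                         ground_truth_netstobg = NA_real_,
                         source = "simulated") {
  counts <- as.numeric(counts)
  if (length(counts) != calibration$n_channels)
    stop(sprintf("counts length (%d) must equal calibration n_channels (%d)",
                 length(counts), calibration$n_channels))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (!is.finite(acquisition_time) || acquisition_time <= 0)
    stop("acquisition_time must be positive")
  structure(
    list(counts = counts, calibration = calibration,
         acquisition_time = acquisition_time,
         concentration = concentration,
         ground_truth_net = ground_truth_net,
         ground_truth_netstobg = ground_truth_netstobg,
         source = source),
    class = "xrf_spectrum"
  )
}

#' @export
print.xrf_spectrum <- function(x, ...) {
  cat(sprintf("<xrf_spectrum> %d channels, t = %gs, conc = %s wt%%, source = %s\n",
              x$calibration$n_channels, x$acquisition_time,
              format(x$concentration), x$source))
  invisible(x)
}

#' Correct a spectrum for detector efficiency
#'
#' Divides the counts element-wise by a per-channel efficiency curve (the
#' CdTe detection-efficiency correction applied before conventional
#' extraction). The default all-ones curve is the identity.
#'
#' @param s An `xrf_spectrum`.
#' @param efficiency_curve Strictly positive numeric vector matching the
#'   channel count, or NULL for identity.
#' @return The corrected `xrf_spectrum`.
#' @export
apply_efficiency_correction <- function(s, efficiency_curve = NULL) {
  stopifnot(inherits(s, "xrf_spectrum"))
  if (is.null(efficiency_curve)) return(s)
  if (length(efficiency_curve) != s$calibration$n_channels)
    stop("efficiency_curve length must match the channel count")
  if (any(!is.finite(efficiency_curve)) || any(efficiency_curve <= 0))
    stop("efficiency_curve must be strictly positive")
  s$counts <- s$counts / efficiency_curve
  s
}

#' Slice the CNN input window from a full spectrum
#'
#' Returns channels 200..699 (0-based, half-open `[200, 700)`), the 500-value
#' window spanning 32--112 keV that the spectral network consumes.
#'
#' @param s An `xrf_spectrum` with 800 channels, or a numeric vector of
#'   length 800.
#' @return Numeric vector of length 500.
#' @export
slice_input_window <- function(s) {
  counts <- if (inherits(s, "xrf_spectrum")) s$counts else as.numeric(s)
  if (length(counts) != 800L)
    stop("slice_input_window expects an 800-channel spectrum")
  counts[201:700]
}

## Batch container ------------------------------------------------------------

#' A set of spectra sharing one calibration
#'
#' Thin matrix-backed container used for dataset-scale operations (one row per
#' spectrum). `meta` carries id, acquisition_time, concentration,
#' ground_truth_net, ground_truth_netstobg and source columns.
#'
#' @param counts Numeric matrix, spectra in rows, channels in columns.
#' @param meta A data.frame with one row per spectrum.
#' @param calibration Shared `energy_calibration`.
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(counts, meta, calibration = energy_calibration()) {
  counts <- as.matrix(counts)
  if (ncol(counts) != calibration$n_channels)
    stop("counts must have one column per calibrated channel")
  if (nrow(counts) != nrow(meta))
    stop("meta must have one row per spectrum")
  structure(list(counts = counts, meta = meta, calibration = calibration),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra x %d channels\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Number of spectra in a set
#' @param x A `spectrum_set`.
#' @param ... Unused.
#' @export
length.spectrum_set <- function(x) nrow(x$counts)

#' Extract one spectrum from a set
#'
#' @param set A `spectrum_set`.
#' @param i Row index.
#' @return An `xrf_spectrum`.
#' @export
set_spectrum <- function(set, i) {
  stopifnot(inherits(set, "spectrum_set"))
  m <- set$meta[i, , drop = FALSE]
  xrf_spectrum(set$counts[i, ], set$calibration,
               acquisition_time = m$acquisition_time,
               concentration = m$concentration,
               ground_truth_net = m$ground_truth_net,
               ground_truth_netstobg = m$ground_truth_netstobg,
               source = as.character(m$source))
}

#' Write a spectrum set as delimited text
#'
#' One spectrum per row: metadata columns (id, acquisition_time,
#' concentration, ground_truth_net, ground_truth_netstobg, source) followed by
#' the 800 channel columns `ch0..ch799`.
#'
#' @param set A `spectrum_set`.
#' @param path Output file.
#' @export
write_spectra <- function(set, path) {
  stopifnot(inherits(set, "spectrum_set"))
  counts <- as.data.frame(set$counts)
  names(counts) <- paste0("ch", seq_len(ncol(counts)) - 1L)
  utils::write.csv(cbind(set$meta, counts), path, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum set written by [write_spectra()]
#'
#' @param path Input file.
#' @param calibration Calibration to attach (default benchtop 800 x 0.16 keV).
#' @return A `spectrum_set`.
#' @export
read_spectra <- function(path, calibration = energy_calibration()) {
  df <- utils::read.csv(path, check.names = FALSE)
  ch_cols <- grep("^ch[0-9]+$", names(df))
  spectrum_set(as.matrix(df[, ch_cols]), df[, -ch_cols, drop = FALSE],
               calibration)
}
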