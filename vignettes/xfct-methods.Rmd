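---
title: "Methods: deep-learning signal extraction and image reconstruction for benchtop XFCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deep-learning signal extraction and image reconstruction for benchtop XFCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xfct)
```

## The problem

Benchtop X-ray fluorescence computed tomography (XFCT) images the spatial
distribution of gold nanoparticles (GNPs) in small objects by exciting gold
K-shell fluorescence with a polychromatic X-ray beam and recording
energy-resolved photon spectra with a CdTe detector at many angular and
translational positions. Two bottlenecks dominate the conventional
processing chain:

1. **Signal extraction.** Each measured spectrum mixes the gold
   K-alpha doublet (~67.0 and ~68.8 keV) with a large Compton-scatter
   continuum. The conventional route fits and subtracts that continuum, sums
   the net counts under the K-alpha peaks, discards statistically
   insignificant results (the 1.96-sigma rule), and normalises the net
   signal by the Compton background under the peaks — the *netSToBg* ratio —
   which doubles as a first-order attenuation correction because signal and
   background are attenuated similarly along the beam path.
2. **Reconstruction.** The per-position netSToBg values form a sinogram
   (30 angles x 11 translations for a full 360-degree scan at 12-degree
   steps and 3 mm translation spacing) that is classically inverted with
   filtered back projection (FBP) or ordered-subsets
   expectation-maximisation (OSEM). Both degrade rapidly as the number of
   projections — and hence scan time and X-ray dose, 21.3 cGy/min at the
   isocenter — is reduced.

This package implements the deep-learning replacement for both steps — a 1D
convolutional network regressing netSToBg directly from the raw 500-channel
spectrum window, and a constant-width 2D U-Net mapping 256 x 256 sinograms
to concentration images — together with the conventional chain it is
benchmarked against, a synthetic data world to validate on, and the full
evaluation suite (MAE, RMSE, R², Huber, SSIM, PSNR, Bland–Altman,
scan-time/dose accounting).

## The synthetic spectrum world

No measured spectra ship with the package, so validation rests on a
generative model whose ground truth is known by construction
(`simulate_spectrum()`, `simulate_spectra()`):

* **Energy axis**: 800 channels of 0.16 keV starting at 0 keV, so channels
  200–700 span exactly 32–112 keV; all learning uses that 500-channel
  window.
* **Continuum**: a single smooth asymmetric hump, log-normal in energy,
  peaking near 48 keV — qualitatively the Compton bump produced by a
  Sn-filtered 125 kVp beam after scattering. Its amplitude (default 100
  counts/s/channel at the mode) sets the background level. The functional
  family is a package choice; nothing authoritative prescribes it, and the
  extraction stage never assumes it (it fits a polynomial in log-energy).
* **Signal**: the gold K-alpha doublet at the tabulated emission energies
  68.804 and 66.990 keV with a 2:1 amplitude ratio, Gaussian-broadened with
  a 0.5 keV detector response. Its area is
  `concentration x 3000 counts/(wt% s) x acquisition_time`, sized so that a
  0.01 wt% sample at 5 s sits at the edge of the 1.96-sigma detection limit
  — matching the instrument's reported sensitivity regime of a few
  hundredths of a percent by weight.
* **Acquisition conditions**: concentrations log-uniform on 0.01–1.0 wt%
  with ~15% gold-free blanks, acquisition times drawn from {5, 10, 20, 60} s
  (the measured corpus' noise ladder), Poisson counting noise.

What a green test on this world establishes: that the implementations of
extraction, training and reconstruction are correct and that the learning
problem the protocol poses is solvable at the stated accuracy. What it does
not establish: performance on real detector data, which additionally
contains escape peaks, pile-up, per-pixel response variations and
beam-hardening structure that the generator deliberately omits.

## The five augmentation operators

`augment_spectrum()` / `augment_spectra()` implement baseline shift, slope
shift, multiplicative gain ("multi-shift scaling"), ±1-channel peak shift
and additive Gaussian noise, applied in the order
`clip0(scale * shift_k(counts) + baseline + slope * channel + noise)`.
Magnitude defaults (±20 counts baseline, ±0.05 counts/channel slope,
gain 0.9–1.1, noise sd 10 counts) are package choices sized against spectra
with a few hundred counts per channel; nothing authoritative states them,
and they are all exposed in `augmentation_config()`. Negative counts are
clipped to zero (counts are physical). The true net signal transforms as
the physics dictates: gain rescales it, baseline/slope/shift/noise perturb
only background and calibration. The training *target*, however, is not the
propagated truth but the conventional extraction re-run on each augmented
spectrum — exactly the reference protocol, whose "ground truth" is the
deconvolution-chain output. Replicate draws are derived from
(seed, spectrum index, replicate index), so any subset of the corpus is
reproducible in isolation.

## Conventional extraction

`fit_compton_background()` fits a degree-4 polynomial in log-energy to the
log counts of all analysis-window channels outside the K-alpha windows
(±3 peak sigmas around each line, merged — 30 channels at the defaults) and
evaluates it everywhere; for a noise-free log-normal continuum the family
contains the truth and the fit is exact. This deliberately replaces the
full detector-response deconvolution of the reference chain — the contract
downstream stages need is only the smooth background under the peaks. The
background fluctuation is estimated as the residual standard deviation over
non-peak channels scaled by the square root of the window size
(Poisson-style aggregation), the 1.96-sigma rule zeroes insignificant
results, and insignificant spectra are *kept* with target 0 so the network
sees near-detection-limit behaviour. On noise-free synthetic spectra the
extracted net counts agree with the generator's doublet area within 2%
(tested), tying the two worlds together.

## The spectral 1D CNN

`build_cnn()` / `train_cnn()` implement the optimised architecture: input
(500, 1) → Gaussian-noise layer (training only) → Conv1D(75 filters,
kernel 39, ELU) → Conv1D(14, 13, ELU) → dropout 0.22 → flatten → dense 260
(ELU) → dense 1 (linear); Huber loss, Adam at 5.4e-5, batch 128, at most
100 epochs with early stopping after 20 non-improving validation epochs and
restoration of the best weights. Inputs are z-scored per channel and
targets z-scored with their own scaler, both fitted on the training split
only (scaler state is checksummed, and prediction verifies the checksum);
predictions are inverse-transformed.

Package decisions where the protocol is silent: Huber delta 1.0 (the
conventional default), Gaussian-noise layer sd 0.01 in scaled units placed
immediately after the input, dense-260 activation ELU (the model's single
stated activation), dropout applied element-wise after the second
convolution. The 70/30 test split and 80/20 validation split use
floor/remainder arithmetic, which reproduces the reference corpus counts
(72,800 → 50,960/21,840 → 40,768/10,192) exactly.

There is no deep-learning framework in the dependency set: the network is
implemented directly on BLAS GEMM in single precision (Rcpp/Armadillo),
with the second convolution evaluated as offset GEMMs over the
batch-concatenated feature axis rather than an explicit im2col — this is
what makes a ~15-minute full-protocol training run feasible on one CPU.
Training is deterministic given the seed in single-threaded mode.

## Tomographic data

Phantoms: `make_3h_phantom()` rasterises the 30 mm three-hole cylinder
(6 mm holes on a 9 mm ring at 120-degree spacing) with acrylic background
at 0 wt% (matrix gold content is below the detection limit; any display
floor is cosmetic only); `make_organ_phantom()` rasterises a generic
elliptical "mouse slice" (paired kidneys at 4.9 wt% — the renal uptake
level, a 0.4 wt% tumor, liver/spleen/heart/lungs at intermediate values),
jittered per seed. It is a synthetic stand-in for a voxelised animal atlas,
not a registered anatomy.

The forward projector (`radon_project()`) is pixel-driven with bilinear
splatting onto the detector axis; the backprojector is its exact adjoint.
Two consequences are load-bearing: every projection row sums exactly to the
image mass (tested to 0.01%), and multiplicative EM updates are
mass-consistent, so OSEM's convergence diagnostics are meaningful.
Reconstruction works in 2D slices only; the 15 mm hole depth never enters.

Sparse-view datasets reduce 30-angle sinograms by uniform-in-angle
subsampling (`reduce_projections()`, rows at `round(i*n/k)`). The 20
projection-count settings are uniformly spaced integers from 30 down to 5
(`projection_settings()`), the choice that makes 292 base images produce
exactly 5,840 pairs; the set is a package inference — only its size is
pinned. Reduced sinograms are stretched (bilinear, constant-preserving) to
the fixed network input rather than zero-filled, because the network has
one input size across all projection counts. Pair augmentation restricts
rotations to multiples of the angular step (an exact sinogram row roll) and
maps flips to exact projection re-indexings — horizontal flip sends angle
theta to (180 − theta) mod 360 — verified against the projector in the
tests; multiplicative scaling uses Radon linearity; Gaussian noise touches
the sinogram only, leaving the ground-truth image clean.

## The constant-width U-Net

`build_unet()` describes a five-level encoder–decoder with a constant 64
feature maps at every depth (sinogram-to-image mapping does not need the
doubling-width semantic capacity of natural-image U-Nets; skip connections
carry the low-level structure). The public implementation family this
descends from fixes the remaining free choices: batch normalisation before
every convolution except the stem and head, transpose-convolution (3x3,
stride 2) upsampling, and a 96-filter convolution immediately after each
skip concatenation, then 96→64→64. With a 1x1 linear output head the
parameter count is exactly **1,616,289** — counting four per-channel batch
-norm parameters (scale, shift, moving mean and variance), i.e. the "total
parameters" convention of deep-learning frameworks. That printed count is
the single constraint that pins the layout, and it is asserted as a hard
unit test.

Training (`train_unet()`): MAE loss, Adam at 1e-4, batch 128, 50 epochs, no
early stopping; inputs and targets min–max scaled to [0, 1] by *separate*
global scalers fitted on the training split (sinogram line integrals and
concentration maps live on very different scales; one joint scaler would
crush the image targets into a few percent of the unit interval). Output is
linear, clipped to [0, 1] at inference only, then inverse-transformed.
Validation history logs MAE, RMSE, PSNR (epoch-level) and SSIM on a
16-image validation subset.

## Classical baselines and quantification

`fbp_reconstruct()` uses the canonical discrete Ram-Lak filter
(spatial-domain ramp response, zero-padded FFT) with the pi/(2 n_angles)
angular weight — over 360-degree coverage every line is sampled twice and
the 1/n_angles weight absorbs it — and zeroes pixels outside the inscribed
circle, which a detector of the image's own width cannot determine.
`osem_reconstruct()` runs multiplicative EM over round-robin angle subsets
(defaults: 5 subsets, 10 iterations, uniform positive start) on the exactly
adjoint projector pair; non-negativity is structural, and an iteration log
records data-vs-model mass. `fit_calibration()` fits intensity→wt% least
squares through the origin (linear by default — XRF signal is linear in
concentration at these loadings); `quantify_roi()` reports mean ± SD over a
mask. `scan_dose()` implements the exact protocol arithmetic
(`time = projections x seconds/60`, `dose = time x 21.3 cGy/min`) with
round-half-up presentation at two decimals — base R's banker's rounding
would mis-round half the table's cells.

## Numerical choices and degenerate inputs

* Single precision throughout the networks (the standard deep-learning
  precision); everything else double.
* Background fit floors counts at 1e-8 before the log; all-zero spectra
  yield an identically-zero background.
* Zero fitted background with positive net counts is flagged degenerate and
  reported with ratio 0 plus a warning.
* The SSIM implementation uses the original windowed formulation (11x11
  Gaussian, sigma 1.5, K1 = 0.01, K2 = 0.03) over windows fully inside the
  image, with the data range always passed explicitly.
* Identical seeds give bit-identical simulations, augmentations, splits and
  trained weights (single-threaded); every stage of `run_end_to_end()`
  records its seed and an MD5 fingerprint of its output.
* R-squared with constant truth is reported as NA with a flag, PSNR of
  identical images as +Inf.

## Scaled-down validation runs

Two training runs back the acceptance checks, both far smaller than the
reference experiments but structurally identical:

* `experiment_cnn_recovery()` — 36 base spectra x 200 augmentations = 7,200
  spectra (the stated floor is 5,000) through the full optimised protocol.
  Undertraining is the binding constraint at this scale (the full corpus
  provides ~13x more optimiser steps at the same tiny learning rate), which
  is why the corpus is sized above the floor rather than at it.
* `experiment_unet_vs_fbp()` — a reduced instance of the U-Net architecture
  (32 x 32 grid, depth 3, 8 features, learning rate raised to 3e-3 for the
  short run) trained on a 500-pair three-hole corpus across the projection
  ladder; the claim checked is the ordering that survives scaling — the
  network reconstructs every held-out sparse-view phantom (10/7/5
  projections) at least as well as FBP — rather than any absolute SSIM
  level, which is not comparable across scales. Two scaling lessons are
  deliberate: the MAE loss needs thousands of optimiser steps before sparse
  structures emerge (validation MAE falls early while RMSE stays flat — the
  network learns the background first), and a corpus mixing 4.9 wt% organ
  phantoms with sub-1 wt% three-hole phantoms under one global scaler
  starves the low-range family at small step budgets. The full-scale run
  (29,200 mixed pairs at 256 x 256) is an hours-long GPU-class computation
  and is reachable with the same code by passing the default
  `unet_config()` and `n_organ > 0`.

## Known limitations

* The spectrum generator omits escape peaks, pile-up, detector-response
  tails and beam hardening; the extraction stage is validated against the
  generator, not against a physical deconvolution.
* The organ phantom is a cartoon of a mouse slice; no atlas registration.
* The system model is parallel-beam; the physical instrument's cone-beam
  and detector's-eye-view geometry are approximated by it, so the OSEM
  baseline here is standard OSEM, not the detector's-eye-view variant.
* Attenuation enters only through the netSToBg normalisation; the forward
  model does not attenuate.
* Full-scale U-Net training on one CPU is impractical; the package trains
  reduced instances and exposes the full configuration for capable
  hardware.
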