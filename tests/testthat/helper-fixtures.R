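## Shared fixtures, built in code. Sizes are deliberately small; the
## full-scale protocol numbers are exercised arithmetically where exact
## counts matter.

noise_free_params <- function(...) {
  spectrum_model_params(noise_model = "none", ...)
}

## a small spectrum set with analytic ground truth
tiny_spectrum_set <- function(n = 6, seed = 101, noise = "poisson") {
  simulate_spectra(n, seed = seed,
                   params = spectrum_model_params(noise_model = noise))
}

## smooth radially symmetric phantom (for FBP inversion properties)
smooth_phantom <- function(n = 64, sigma = 8) {
  xy <- seq_len(n) - (n + 1) / 2
  phantom_image(exp(-outer(xy^2, xy^2, "+") / (2 * sigma^2)), 36 / n)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-12), tol)
}
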