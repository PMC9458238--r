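# Small simulation configurations shared across test files. Reduced m/z range
# and channel counts keep single tests fast; the acceptance tests use larger
# problem sizes.

tiny_config <- function(..., seed = 1L) {
  defaults <- list(mz_min = 700, mz_max = 1000, n_channels = 601L,
                   n_peaks = 30L, peak_sigma_range = c(1, 2),
                   roi_shape = c(12L, 12L), n_clusters_per_roi = 3L,
                   seed = seed)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# Noise-free, drift-free variant: pixel spectra are exact mixture sums.
clean_config <- function(..., seed = 1L) {
  defaults <- list(baseline_amplitude = 0, tic_cv = 0, noise_sd = 0,
                   outlier_fraction = 0, seed = seed)
  do.call(tiny_config, utils::modifyList(defaults, list(...)))
}

# Gaussian profile on an axis (unit area), used to construct exact spectra.
gauss_profile <- function(mz, mu, sigma) dnorm(mz, mu, sigma)

# Adjusted Rand index between two labelings (oracle from mclust).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
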