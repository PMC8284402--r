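# Shared fixtures: all synthetic, built in code at test time.
# Reference imaging conditions: 12.4 keV (lambda = 1e-10 m) on a 1 um
# effective pixel grid -- a generic parallel-equivalent microtomography
# setting used throughout the numerical tests.

WL <- 1e-10
PIX <- 1e-6

# Zero-mean Gaussian-correlated random field, peak-normalized to `amp`.
# `sigma_px` sets the correlation length, i.e. the finest feature scale.
grf <- function(n, sigma_px, amp, seed) {
  set.seed(seed)
  f <- holopr:::gaussian_blur(matrix(stats::rnorm(n * n), n), sigma_px)
  f <- f - mean(f)
  amp * f / max(abs(f))
}

# Full-Fresnel simulated stack of an object at the given distances.
simulate_fresnel <- function(obj, distances, wavelength = WL) {
  u <- as_wavefield(obj)
  imgs <- lapply(distances, function(d)
    intensity(fresnel_propagate(u, wavelength, d)))
  hologram_stack(imgs, distances, obj$pixel, wavelength)
}

# Weak mixed-contrast phantom (phase + absorption), correlation 4 px.
weak_object <- function(n, phi_max = 0.01, b_max = 0.005,
                        seeds = c(10, 11)) {
  phi <- grf(n, 4, phi_max, seeds[1])
  b <- pmax(grf(n, 4, b_max / 2, seeds[2]) + b_max / 2, 0)
  object_maps(phi, b, PIX)
}

# Smooth pure-phase blob with exactly compact support, plus its mask
# (the object is exactly background outside the support).
blob_phase <- function(n = 64, depth = -0.5, seed = 30) {
  set.seed(seed)
  blob <- matrix(0, n, n)
  blob[(3 * n / 8):(5 * n / 8), (3 * n / 8):(5 * n / 8)] <- 1
  blob <- holopr:::gaussian_blur(blob, 3)
  phi <- depth * blob / max(blob)
  phi[abs(phi) < 1e-3 * max(abs(phi))] <- 0
  list(obj = object_maps(phi, NULL, PIX), support = phi != 0)
}

# NanoMAX-like geometry used for the worked-example checks.
nanomax_geometry <- function() {
  acquisition_geometry(13, z1_m = 10.1e-3, zd_m = 1.12, pixel_m = 650e-9)
}
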