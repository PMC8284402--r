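# Synthetic phantoms and multi-distance hologram simulation: the test-data
# backbone standing in for beamline acquisitions.
#
# The simulator works in the Fresnel-scaled parallel-equivalent frame: the
# exit wave is formed once on the phantom's (effective) pixel grid and
# propagated over each effective distance D_n = z1 (zD - z1) / zD derived
# from the sample positions. Counting (Poisson) noise is the only noise
# source by default; an optional smooth multiplicative flat per distance
# exercises the flat-correction path.

#' Phantom: projected thickness of a known material
#'
#' @param thickness Non-negative thickness map (m).
#' @param delta,beta Refractive index decrement and absorption index of the
#'   (single) material; `n = 1 - delta + i*beta`.
#' @param pixel Pixel size (m).
#' @return Object of class `phantom`.
#' @export
phantom <- function(thickness, delta, beta, pixel) {
  thickness <- as.matrix(thickness)
  if (any(thickness < 0)) stop("thickness must be non-negative")
  if (beta < 0) stop("beta must be non-negative")
  if (pixel <= 0) stop("pixel must be positive")
  structure(list(thickness = thickness, delta = delta, beta = beta,
                 pixel = pixel), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "<phantom> %d x %d, pixel %.4g m, t_max %.4g m, delta/beta %.4g\n",
    nrow(x$thickness), ncol(x$thickness), x$pixel, max(x$thickness),
    if (x$beta > 0) x$delta / x$beta else Inf))
  invisible(x)
}

#' Disc (projected sphere) phantom
#'
#' Sum of spherical-cap projected thicknesses
#' `t(x) = 2 sqrt(r^2 - |x - c|^2)`, each disc rescaled so its centre
#' thickness is `t_max`. Overlapping discs add; discs must fit in the grid.
#'
#' @param shape `c(ny, nx)` grid size.
#' @param centers Matrix with one `(row, col)` centre per disc (pixels,
#'   1-based), or a length-2 vector for a single disc.
#' @param radii Disc radii in pixels (recycled).
#' @param t_max Centre thickness per disc (m, recycled).
#' @param delta,beta Material constants.
#' @param pixel Pixel size (m).
#' @param edge_sigma Gaussian smoothing of the thickness map, in pixels
#'   (0 = hard spherical edge). Sets the finest feature size of the phantom.
#' @return A [phantom].
#' @export
make_disc_phantom <- function(shape, centers, radii, t_max, delta, beta,
                              pixel, edge_sigma = 0) {
  ny <- shape[1]; nx <- shape[2]
  centers <- matrix(centers, ncol = 2)
  ndisc <- nrow(centers)
  radii <- rep_len(radii, ndisc)
  t_max <- rep_len(t_max, ndisc)
  t <- matrix(0, ny, nx)
  rowg <- matrix(seq_len(ny), ny, nx)
  colg <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  for (i in seq_len(ndisc)) {
    cy <- centers[i, 1]; cx <- centers[i, 2]; r <- radii[i]
    if (cy - r < 1 || cy + r > ny || cx - r < 1 || cx + r > nx)
      stop("disc extends outside the grid")
    rho2 <- (rowg - cy)^2 + (colg - cx)^2
    cap <- ifelse(rho2 <= r^2, sqrt(pmax(1 - rho2 / r^2, 0)), 0)
    t <- t + t_max[i] * cap
  }
  if (edge_sigma > 0) t <- pmax(gaussian_blur(t, edge_sigma), 0)
  phantom(t, delta, beta, pixel)
}

#' Siemens-star (spoke) resolution phantom
#'
#' Binary spoke pattern `sin(n_spokes * theta) > 0` inside an annulus; the
#' spoke width shrinks linearly towards the centre, probing all length
#' scales like the classical star test pattern.
#'
#' @param shape `c(ny, nx)` grid size.
#' @param n_spokes Number of spoke pairs; 0 gives an empty phantom.
#' @param r_inner,r_outer Annulus radii in pixels; default 2 and
#'   `0.45 * min(shape)`.
#' @param t_max Thickness of the spokes (m).
#' @param delta,beta Material constants.
#' @param pixel Pixel size (m).
#' @return A [phantom].
#' @export
make_star_phantom <- function(shape, n_spokes, r_inner = 2,
                              r_outer = 0.45 * min(shape), t_max = 1e-6,
                              delta = 1e-6, beta = 1e-8, pixel = 1e-6) {
  ny <- shape[1]; nx <- shape[2]
  if (n_spokes < 0) stop("n_spokes must be >= 0")
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  y <- matrix(seq_len(ny) - cy, ny, nx)
  x <- matrix(seq_len(nx) - cx, ny, nx, byrow = TRUE)
  r <- sqrt(x^2 + y^2)
  t <- matrix(0, ny, nx)
  if (n_spokes > 0) {
    theta <- atan2(y, x)
    spokes <- sin(n_spokes * theta) > 0
    t[spokes & r >= r_inner & r <= r_outer] <- t_max
  }
  phantom(t, delta, beta, pixel)
}

#' Project a phantom to phase and absorption maps
#'
#' `phi = -(2*pi/lambda) * delta * t`, `B = (2*pi/lambda) * beta * t`.
#'
#' @param ph A [phantom].
#' @param wavelength Wavelength (m).
#' @return An [object_maps].
#' @export
project_phantom <- function(ph, wavelength) {
  stopifnot(inherits(ph, "phantom"))
  k <- 2 * pi / wavelength
  object_maps(phi = -k * ph$delta * ph$thickness,
              B = k * ph$beta * ph$thickness,
              pixel = ph$pixel)
}

# Separable Gaussian blur with periodic boundaries (FFT-based).
gaussian_blur <- function(x, sigma_px) {
  ny <- nrow(x); nx <- ncol(x)
  fy <- fft_freq(ny, 1); fx <- fft_freq(nx, 1)
  g <- outer(exp(-2 * pi^2 * sigma_px^2 * fy^2),
             exp(-2 * pi^2 * sigma_px^2 * fx^2))
  Re(ifft2(fft2(x) * g))
}

# Evaluate an expression with a private, seeded RNG stream; the caller's
# global .Random.seed is untouched (no global random state).
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a multi-distance hologram acquisition
#'
#' For each sample position `z1` in `z1_list`, computes the effective
#' distance via Fresnel scaling, propagates the phantom's exit wave with the
#' full Fresnel operator, and records the intensity. With a finite photon
#' budget `n0_photons`, each pixel is replaced by a Poisson draw with mean
#' `n0 * I`, returned as `counts / n0`; `n0_photons = Inf` is noiseless.
#'
#' @param ph A [phantom] sampled at the effective pixel of the reference
#'   position (see package vignette for the parallel-equivalent convention).
#' @param geometry An [acquisition_geometry]; its `zd` and wavelength are
#'   used. The phantom pixel is taken as the common effective pixel.
#' @param z1_list Sample positions (m), all in `(0, zd]`.
#' @param n0_photons Incident photons per pixel (`Inf` = noiseless).
#' @param seed Integer seed for the Poisson draws (required when noisy);
#'   recorded in the result. The global RNG state is left untouched.
#' @param flat_sigma Relative amplitude of an optional smooth multiplicative
#'   flat-field drawn once per distance (0 = none). When present, the flats
#'   are stored so flat correction can be exercised.
#' @return Object of class `simulated_dataset`: a list with `stack` (a
#'   [hologram_stack] of effective distances), `truth` (the [object_maps]),
#'   `flats` (list or `NULL`), `z1_list`, `n0_photons`, `seed`.
#' @export
simulate_stack <- function(ph, geometry, z1_list, n0_photons = Inf,
                           seed = NULL, flat_sigma = 0) {
  stopifnot(inherits(ph, "phantom"),
            inherits(geometry, "acquisition_geometry"))
  if (any(z1_list <= 0) || any(z1_list > geometry$zd))
    stop("z1 positions must lie in (0, zD]")
  if (!is.infinite(n0_photons) && n0_photons <= 0)
    stop("photon count must be positive (or Inf for noiseless)")
  if ((!is.infinite(n0_photons) || flat_sigma > 0) && is.null(seed))
    stop("a seed is required for noisy simulation")
  wl <- geometry$wavelength
  truth <- project_phantom(ph, wl)
  u <- as_wavefield(truth)
  dists <- vapply(z1_list, function(z) effective_distance(z, geometry$zd),
                  numeric(1))
  images <- lapply(dists, function(d)
    intensity(fresnel_propagate(u, wl, d)))
  flats <- NULL
  run <- function() {
    if (flat_sigma > 0) {
      flats <<- lapply(seq_along(images), function(k) {
        raw <- matrix(stats::rnorm(length(images[[k]])),
                      nrow(images[[k]]))
        1 + flat_sigma * gaussian_blur(raw, 8) /
          stats::sd(gaussian_blur(raw, 8))
      })
      images <<- Map(`*`, images, flats)
    }
    if (!is.infinite(n0_photons)) {
      images <<- lapply(images, function(im) {
        matrix(stats::rpois(length(im), n0_photons * im),
               nrow(im)) / n0_photons
      })
    }
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
  structure(list(
    stack = hologram_stack(images, dists, ph$pixel, wl),
    truth = truth,
    flats = flats,
    z1_list = z1_list,
    n0_photons = n0_photons,
    seed = seed
  ), class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(
    "<simulated_dataset> %d distance(s), n0 = %s, seed = %s\n",
    length(x$stack$images), format(x$n0_photons),
    if (is.null(x$seed)) "none" else x$seed))
  print(x$stack)
  invisible(x)
}
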