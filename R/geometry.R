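# Cone-beam acquisition geometry and Fresnel-scaling conversions.
#
# A divergent-beam (cone-beam) acquisition with focus-to-sample distance z1
# and focus-to-detector distance zD is equivalent, by the Fresnel scaling
# theorem, to a parallel-beam acquisition over the effective distance
# D = z1 (zD - z1) / zD, sampled at the demagnified pixel p / M with
# M = zD / z1. All retrieval code in this package works in that
# parallel-equivalent frame.

# hc in keV * m, CODATA-rounded; fixed constant for reproducibility.
.hc_kev_m <- 1.23984193e-9

#' Photon wavelength from energy
#'
#' `lambda[m] = 1.23984193e-9 / E[keV]`.
#'
#' @param energy_kev Photon energy in keV (> 0).
#' @return Wavelength in metres.
#' @export
energy_to_wavelength <- function(energy_kev) {
  if (!is.numeric(energy_kev) || any(energy_kev <= 0))
    stop("energy must be positive (keV)")
  .hc_kev_m / energy_kev
}

#' Geometric magnification of a cone-beam setup
#'
#' @param z1 Focus-to-sample distance (m), 0 < z1 <= zD.
#' @param zd Focus-to-detector distance (m).
#' @return `zd / z1` (dimensionless, >= 1).
#' @export
magnification <- function(z1, zd) {
  check_distances(z1, zd)
  zd / z1
}

#' Effective (parallel-equivalent) propagation distance
#'
#' Fresnel scaling: cone-beam data recorded at `(z1, zd)` behave as
#' parallel-beam data propagated over `D = z1 (zd - z1) / zd`. `D` is 0 at
#' the contact plane (`z1 = zd`) and maximal (`zd/4`) at `z1 = zd/2`.
#'
#' @inheritParams magnification
#' @return Effective distance in metres.
#' @export
effective_distance <- function(z1, zd) {
  check_distances(z1, zd)
  z1 * (zd - z1) / zd
}

#' Effective (demagnified) pixel size
#'
#' @param p Detector pixel size (m), > 0.
#' @param m Geometric magnification, >= 1.
#' @return `p / m` in metres.
#' @export
effective_pixel <- function(p, m) {
  if (!is.numeric(p) || any(p <= 0)) stop("pixel size must be positive")
  if (!is.numeric(m) || any(m < 1)) stop("magnification must be >= 1")
  p / m
}

#' Fresnel number of a feature
#'
#' `F = a^2 / (lambda * L)` for feature size `a`, wavelength `lambda` and
#' propagation distance `L`. `F ~ 1` marks the edge-enhancement regime
#' (TIE-type methods valid), `F << 1` the holographic regime (CTF-type and
#' iterative methods required).
#'
#' @param a Feature size (m).
#' @param wavelength Wavelength (m).
#' @param distance Propagation distance (m).
#' @return Dimensionless Fresnel number.
#' @export
fresnel_number <- function(a, wavelength, distance) {
  if (any(c(a, wavelength, distance) <= 0))
    stop("fresnel_number: all arguments must be strictly positive")
  a^2 / (wavelength * distance)
}

check_distances <- function(z1, zd) {
  if (!is.numeric(z1) || !is.numeric(zd) || any(z1 <= 0) || any(zd <= 0) ||
      any(z1 > zd))
    stop("invalid geometry: need 0 < z1 <= zD")
  invisible(TRUE)
}

#' Acquisition geometry of a cone-beam imaging setup
#'
#' Bundles the beamline parameters and derives wavelength, magnification,
#' effective propagation distance and effective pixel size.
#'
#' @param energy_kev Photon energy (keV).
#' @param z1_m Focus-to-sample distance (m).
#' @param zd_m Focus-to-detector distance (m).
#' @param pixel_m Detector pixel size (m).
#' @return An object of class `acquisition_geometry`: a list with fields
#'   `energy_kev`, `wavelength`, `z1`, `zd`, `pixel`, and derived
#'   `magnification`, `effective_distance`, `effective_pixel`.
#' @examples
#' g <- acquisition_geometry(13, z1_m = 10.1e-3, zd_m = 1.12,
#'                           pixel_m = 650e-9)
#' round(g$magnification, 1)        # 110.9
#' round(g$effective_pixel * 1e9)   # 6 nm
#' @export
acquisition_geometry <- function(energy_kev, z1_m, zd_m, pixel_m) {
  check_distances(z1_m, zd_m)
  if (pixel_m <= 0) stop("pixel size must be positive")
  wl <- energy_to_wavelength(energy_kev)
  m <- magnification(z1_m, zd_m)
  structure(list(
    energy_kev = energy_kev,
    wavelength = wl,
    z1 = z1_m,
    zd = zd_m,
    pixel = pixel_m,
    magnification = m,
    effective_distance = effective_distance(z1_m, zd_m),
    effective_pixel = effective_pixel(pixel_m, m)
  ), class = "acquisition_geometry")
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat("<acquisition_geometry>\n")
  cat(sprintf("  energy       : %.4g keV  (lambda = %.4g m)\n",
              x$energy_kev, x$wavelength))
  cat(sprintf("  z1, zD       : %.4g m, %.4g m\n", x$z1, x$zd))
  cat(sprintf("  magnification: %.4g\n", x$magnification))
  cat(sprintf("  eff. distance: %.4g m\n", x$effective_distance))
  cat(sprintf("  pixel        : %.4g m (detector), %.4g m (effective)\n",
              x$pixel, x$effective_pixel))
  invisible(x)
}
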