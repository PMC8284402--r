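# Forward models: full Fresnel propagation of a complex wavefield and its
# CTF (weak-object) and TIE (short-distance) linearizations.
#
# Conventions, fixed once and validated against each other by the tests:
#   exit wave            u = exp(-B + i*phi)
#   Fresnel transfer fn  H_D(f) = exp(-i * chi_D(f)),  chi = pi*lambda*D*|f|^2
#   CTF intensity        I~(f) = delta(f) + 2 sin(chi) phi~ - 2 cos(chi) B~
#   TIE intensity        I_D = I0 - (lambda*D / 2*pi) div(I0 grad phi)
# phi is the phase shift (phi <= 0 for delta > 0 under the usual sign
# convention), B >= 0 the absorption exponent, I0 = exp(-2B) the
# contact-plane intensity.

#' Complex wavefield on a square-pixel grid
#'
#' @param values Complex (or numeric) matrix, at least 8 x 8, all finite.
#' @param pixel Pixel size (m).
#' @return Object of class `wavefield` with fields `values` and `pixel`.
#' @export
wavefield <- function(values, pixel) {
  values <- as.matrix(values)
  if (!is.complex(values)) storage.mode(values) <- "complex"
  if (nrow(values) < 8 || ncol(values) < 8)
    stop("wavefield must be at least 8 x 8")
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values))))
    stop("wavefield values must be finite")
  if (!is.numeric(pixel) || length(pixel) != 1 || pixel <= 0)
    stop("pixel must be a single positive number (square pixels)")
  structure(list(values = values, pixel = pixel), class = "wavefield")
}

#' @export
print.wavefield <- function(x, ...) {
  cat(sprintf("<wavefield> %d x %d, pixel %.4g m, mean |u|^2 = %.6g\n",
              nrow(x$values), ncol(x$values), x$pixel,
              mean(Mod(x$values)^2)))
  invisible(x)
}

#' Object maps: phase shift and absorption exponent
#'
#' The projected object is described by the phase shift
#' `phi = -(2*pi/lambda) * integral(delta) dz` (radians, <= 0 for delta > 0)
#' and the absorption exponent `B = (2*pi/lambda) * integral(beta) dz >= 0`,
#' so the exit wave is `u = exp(-B + i*phi)` and the contact-plane intensity
#' `I0 = exp(-2B)`.
#'
#' @param phi Phase map (radians), matrix.
#' @param B Absorption exponent map (dimensionless, >= 0); defaults to 0.
#' @param pixel Pixel size (m).
#' @return Object of class `object_maps`.
#' @export
object_maps <- function(phi, B = NULL, pixel) {
  phi <- as.matrix(phi)
  if (is.null(B)) B <- array(0, dim(phi))
  B <- as.matrix(B)
  if (!identical(dim(phi), dim(B))) stop("phi and B must share shape")
  if (any(B < 0)) stop("absorption exponent B must be non-negative")
  structure(list(phi = phi, B = B, pixel = pixel), class = "object_maps")
}

#' Exit wave of an object
#'
#' @param obj An [object_maps] object.
#' @return A [wavefield] `u = exp(-B + i*phi)`.
#' @export
as_wavefield <- function(obj) {
  stopifnot(inherits(obj, "object_maps"))
  u <- exp(matrix(complex(real = -obj$B, imaginary = obj$phi),
                  nrow(obj$phi)))
  wavefield(u, obj$pixel)
}

# Accept either a wavefield or a plain matrix + pixel.
as_field_matrix <- function(u, pixel = NULL) {
  if (inherits(u, "wavefield")) list(values = u$values, pixel = u$pixel)
  else {
    if (is.null(pixel)) stop("pixel size required for a plain matrix")
    list(values = as.matrix(u), pixel = pixel)
  }
}

#' Fresnel propagation of a wavefield
#'
#' Single-FFT transfer-function implementation:
#' `u_D = IDFT[ H_D * DFT[u] ]` with `H_D(f) = exp(-i*pi*lambda*D*|f|^2)`.
#' The operator is unitary (total intensity conserved) and composes as
#' `propagate(D1) o propagate(D2) = propagate(D1 + D2)`. Negative `distance`
#' back-propagates.
#'
#' The unpadded operator assumes a periodic field; for non-periodic data set
#' `pad = TRUE` to reflect-pad to twice the size before propagation and crop
#' afterwards (this trades exact unitarity for suppressed wrap-around).
#'
#' @param u A [wavefield] (or a complex matrix, with `pixel` given).
#' @param wavelength Wavelength (m).
#' @param distance Propagation distance (m); any sign.
#' @param pixel Pixel size (m), only needed when `u` is a bare matrix.
#' @param pad Reflect-pad to 2x size before propagating (default `FALSE`).
#' @return A [wavefield] of the same shape.
#' @export
fresnel_propagate <- function(u, wavelength, distance, pixel = NULL,
                              pad = FALSE) {
  fm <- as_field_matrix(u, pixel)
  v <- fm$values
  if (pad) {
    pp <- pad_reflect2x(v)
    chi <- chirp_phase(nrow(pp$values), ncol(pp$values), fm$pixel,
                       wavelength, distance)
    pp$values <- ifft2(exp(complex(imaginary = -chi)) * fft2(pp$values))
    out <- crop_center(pp)
  } else {
    chi <- chirp_phase(nrow(v), ncol(v), fm$pixel, wavelength, distance)
    out <- ifft2(exp(complex(imaginary = -chi)) * fft2(v))
  }
  wavefield(out, fm$pixel)
}

#' Intensity of a wavefield
#'
#' @param u A [wavefield] or complex matrix.
#' @return Numeric matrix `|u|^2`.
#' @export
intensity <- function(u) {
  v <- if (inherits(u, "wavefield")) u$values else u
  Mod(v)^2
}

#' CTF (weak-object) forward intensity model
#'
#' Linearization of the Fresnel intensity in the object contrast: in Fourier
#' space `I~(f) = delta(f) + 2 sin(chi) phi~(f) - 2 cos(chi) B~(f)` with
#' `chi = pi*lambda*D*|f|^2`. Valid for weak phase and absorption; the sign
#' pattern is the one consistent with `u = exp(-B + i phi)` and
#' `H = exp(-i chi)` (validated against [fresnel_propagate] in the tests).
#'
#' @param obj An [object_maps] object.
#' @param wavelength Wavelength (m).
#' @param distance Effective propagation distance (m).
#' @return Numeric intensity matrix.
#' @export
ctf_forward <- function(obj, wavelength, distance) {
  stopifnot(inherits(obj, "object_maps"))
  chi <- chirp_phase(nrow(obj$phi), ncol(obj$phi), obj$pixel,
                     wavelength, distance)
  spec <- 2 * sin(chi) * fft2(obj$phi) - 2 * cos(chi) * fft2(obj$B)
  1 + Re(ifft2(spec))
}

#' TIE (short-distance) forward intensity model
#'
#' Transport-of-intensity linearization in the propagation distance:
#' `I_D = I0 - (lambda*D / (2*pi)) * div(I0 * grad phi)` with
#' `I0 = exp(-2B)`. Gradients are spectral (periodic boundaries). Valid for
#' Fresnel numbers of the finest feature well above 1.
#'
#' @inheritParams ctf_forward
#' @return Numeric intensity matrix.
#' @export
tie_forward <- function(obj, wavelength, distance) {
  stopifnot(inherits(obj, "object_maps"))
  ny <- nrow(obj$phi); nx <- ncol(obj$phi)
  i0 <- exp(-2 * obj$B)
  gx <- spectral_deriv(obj$phi, obj$pixel, axis = "x")
  gy <- spectral_deriv(obj$phi, obj$pixel, axis = "y")
  div <- spectral_deriv(i0 * gx, obj$pixel, axis = "x") +
         spectral_deriv(i0 * gy, obj$pixel, axis = "y")
  i0 - wavelength * distance / (2 * pi) * div
}

# d/dx or d/dy by FFT; frequencies in cycles/m so d/dx <-> i*2*pi*f.
spectral_deriv <- function(x, pixel, axis = c("x", "y")) {
  axis <- match.arg(axis)
  ny <- nrow(x); nx <- ncol(x)
  if (axis == "x") {
    f <- matrix(fft_freq(nx, pixel), ny, nx, byrow = TRUE)
  } else {
    f <- matrix(fft_freq(ny, pixel), ny, nx)
  }
  Re(ifft2(complex(imaginary = 2 * pi) * f * fft2(x)))
}
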