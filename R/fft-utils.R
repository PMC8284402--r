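# Small FFT helpers shared by the propagators and the filter-based methods.
# Frequencies are in cycles per metre throughout (not angular), so every
# chirp/filter below is written in terms of chi = pi * lambda * D * |f|^2.

#' Discrete Fourier transform sample frequencies
#'
#' Frequencies for an `n`-point DFT with sample spacing `d`, in the standard
#' DFT ordering (non-negative frequencies first, then the negative ones),
#' i.e. `k/(n*d)` for `k = 0, 1, ..., ceil(n/2)-1, -floor(n/2), ..., -1`.
#'
#' @param n Number of samples.
#' @param d Sample spacing (m). Frequencies come out in cycles per metre.
#' @return Numeric vector of length `n`.
#' @export
fft_freq <- function(n, d = 1) {
  stopifnot(n >= 1, d > 0)
  k <- c(seq_len(ceiling(n / 2)) - 1L, seq.int(-floor(n / 2), -1L))
  if (n == 1L) k <- 0L
  k / (n * d)
}

# 2-D forward / inverse DFT (stats::fft handles arrays natively).
fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' Squared spatial-frequency grid for an image
#'
#' Returns the matrix `|f|^2 = fx^2 + fy^2` (cycles^2 per m^2) matching the
#' DFT layout of an `ny` x `nx` image sampled at `pixel` metres. Row index is
#' y, column index is x.
#'
#' @param ny,nx Image dimensions.
#' @param pixel Pixel size (m); pixels must be square.
#' @return `ny` x `nx` numeric matrix; the `[1,1]` element (DC) is 0.
#' @export
freq_squared_grid <- function(ny, nx, pixel) {
  fy <- fft_freq(ny, pixel)
  fx <- fft_freq(nx, pixel)
  outer(fy^2, fx^2, `+`)
}

#' Fresnel chirp phase grid
#'
#' The phase `chi_D(f) = pi * lambda * D * |f|^2` (radians) of the Fresnel
#' transfer function on the DFT grid of an image.
#'
#' @inheritParams freq_squared_grid
#' @param wavelength Wavelength (m).
#' @param distance Propagation distance (m); may be negative.
#' @return `ny` x `nx` matrix of chirp phases; 0 at DC.
#' @export
chirp_phase <- function(ny, nx, pixel, wavelength, distance) {
  pi * wavelength * distance * freq_squared_grid(ny, nx, pixel)
}

# Symmetric (edge-reflect) padding of a matrix to double size, and the
# matching crop. Used to suppress wrap-around in the propagator when the
# field is not periodic.
pad_reflect2x <- function(x) {
  ny <- nrow(x); nx <- ncol(x)
  py1 <- floor(ny / 2); py2 <- ny - py1
  px1 <- floor(nx / 2); px2 <- nx - px1
  ridx <- c(rev(seq_len(py1)), seq_len(ny), ny + 1 - seq_len(py2))
  cidx <- c(rev(seq_len(px1)), seq_len(nx), nx + 1 - seq_len(px2))
  list(values = x[ridx, cidx, drop = FALSE], ny = ny, nx = nx,
       oy = py1, ox = px1)
}

crop_center <- function(padded) {
  padded$values[padded$oy + seq_len(padded$ny),
                padded$ox + seq_len(padded$nx), drop = FALSE]
}
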