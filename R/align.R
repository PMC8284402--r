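# Rigid translation alignment by phase correlation, sub-pixel shifts via
# the Fourier shift theorem, and Fourier resampling to a common pixel.
# Deformable (mutual-information) registration is out of scope; phase
# correlation is adequate for simulated data and rigid drifts, and is a
# stated limitation for strongly magnification-mismatched acquisitions.

#' Shift an image by (dy, dx) pixels (Fourier shift theorem)
#'
#' Circular (periodic) shift; integer shifts match a matrix roll exactly,
#' fractional shifts interpolate spectrally. Positive `dy` moves content
#' down, positive `dx` moves it right.
#'
#' @param image Numeric matrix.
#' @param dy,dx Shift in pixels (any real numbers).
#' @return Shifted numeric matrix.
#' @export
apply_shift <- function(image, dy, dx) {
  ny <- nrow(image); nx <- ncol(image)
  # for even sizes the Nyquist bin has no conjugate partner: keep its phase
  # factor real so shifting a real image stays real (integer shifts exact)
  phase1d <- function(n, d) {
    p <- exp(-2i * pi * fft_freq(n, 1) * d)
    if (n %% 2 == 0) p[n / 2 + 1] <- Re(p[n / 2 + 1])
    p
  }
  ph <- outer(phase1d(ny, dy), phase1d(nx, dx))
  Re(ifft2(fft2(image) * ph))
}

# Wrap DFT peak index (1-based) to a signed shift.
wrap_index <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)

# 3-point parabolic sub-pixel refinement around a peak value triple.
parabolic_offset <- function(m1, p, p1) {
  den <- m1 - 2 * p + p1
  if (den == 0) 0 else 0.5 * (m1 - p1) / den
}

#' Translation between two images by phase correlation
#'
#' Peak of the inverse DFT of the normalized cross-power spectrum, refined
#' per axis by a 3-point parabolic fit. If `moving` equals `reference`
#' shifted by `(dy, dx)` (as by [apply_shift]), the return value is
#' `(dy, dx)`.
#'
#' @param reference,moving Numeric matrices of the same shape.
#' @return Numeric `c(dy, dx)` in pixels (possibly fractional).
#' @export
phase_correlation <- function(reference, moving) {
  stopifnot(identical(dim(reference), dim(moving)))
  if (all(reference == 0) || all(moving == 0))
    stop("undefined correlation: all-zero image")
  fr <- fft2(reference); fm <- fft2(moving)
  cross <- fm * Conj(fr)
  mag <- Mod(cross)
  mag[mag == 0] <- 1
  r <- Re(ifft2(cross / mag))
  ny <- nrow(r); nx <- ncol(r)
  pk <- arrayInd(which.max(r), dim(r))
  iy <- pk[1]; ix <- pk[2]
  wrap <- function(i, n) ((i - 1 + n) %% n) + 1
  oy <- parabolic_offset(r[wrap(iy - 1, ny), ix], r[iy, ix],
                         r[wrap(iy + 1, ny), ix])
  ox <- parabolic_offset(r[iy, wrap(ix - 1, nx)], r[iy, ix],
                         r[iy, wrap(ix + 1, nx)])
  c(dy = wrap_index(iy, ny) + oy, dx = wrap_index(ix, nx) + ox)
}

#' Align a list of images to the first by phase correlation
#'
#' @param images List of >= 2 numeric matrices of the same shape, on a
#'   common pixel grid.
#' @return Matrix with one `(dy, dx)` row per image; the first row is
#'   `(0, 0)`. Applying `apply_shift(image, -dy, -dx)` registers an image
#'   onto the first.
#' @export
align_stack <- function(images) {
  if (length(images) < 2) stop("need at least two images to align")
  shp <- dim(images[[1]])
  if (!all(vapply(images, function(m) identical(dim(m), shp), logical(1))))
    stop("all images must share shape")
  ref <- images[[1]]
  out <- t(vapply(images, function(m) {
    if (identical(m, ref)) c(dy = 0, dx = 0) else phase_correlation(ref, m)
  }, numeric(2)))
  rownames(out) <- NULL
  out
}

#' Resample an image to a different pixel size by Fourier pad/crop
#'
#' Keeps the field of view and changes the sampling rate: the spectrum is
#' zero-padded (finer pixel) or cropped (coarser pixel) symmetrically. The
#' output size is `round(n * pixel_in / pixel_out)` per axis, so the
#' achieved pixel may differ from the request by up to half a sample; it is
#' returned in the `"pixel"` attribute.
#'
#' @param image Numeric matrix.
#' @param pixel_in Current pixel size (m).
#' @param pixel_out Requested pixel size (m).
#' @return Resampled matrix with attribute `"pixel"`.
#' @export
resample_to_pixel <- function(image, pixel_in, pixel_out) {
  stopifnot(pixel_in > 0, pixel_out > 0)
  ny <- nrow(image); nx <- ncol(image)
  ny2 <- max(2L, round(ny * pixel_in / pixel_out))
  nx2 <- max(2L, round(nx * pixel_in / pixel_out))
  if (ny2 == ny && nx2 == nx) {
    attr(image, "pixel") <- pixel_in
    return(image)
  }
  sp <- fftshift2(fft2(image))
  out_sp <- matrix(0 + 0i, ny2, nx2)
  cy <- min(ny, ny2); cx <- min(nx, nx2)
  src_y <- floor(ny / 2) - floor(cy / 2) + seq_len(cy)
  src_x <- floor(nx / 2) - floor(cx / 2) + seq_len(cx)
  dst_y <- floor(ny2 / 2) - floor(cy / 2) + seq_len(cy)
  dst_x <- floor(nx2 / 2) - floor(cx / 2) + seq_len(cx)
  out_sp[dst_y, dst_x] <- sp[src_y, src_x]
  out <- Re(ifft2(ifftshift2(out_sp))) * (ny2 * nx2) / (ny * nx)
  attr(out, "pixel") <- pixel_in * ny / ny2
  out
}

fftshift2 <- function(x) {
  ny <- nrow(x); nx <- ncol(x)
  x[c((floor(ny / 2) + 1):ny, 1:floor(ny / 2)),
    c((floor(nx / 2) + 1):nx, 1:floor(nx / 2)), drop = FALSE]
}

ifftshift2 <- function(x) {
  ny <- nrow(x); nx <- ncol(x)
  x[c((ny - floor(ny / 2) + 1):ny, 1:(ny - floor(ny / 2))),
    c((nx - floor(nx / 2) + 1):nx, 1:(nx - floor(nx / 2))), drop = FALSE]
}

#' Align and resample a hologram stack for retrieval
#'
#' Registers every image onto the first by phase correlation and undoes the
#' measured shifts; optionally resamples all images to the smallest pixel
#' first when per-image pixels are supplied.
#'
#' @param stack A [hologram_stack].
#' @param pixels Optional per-image pixel sizes (m); images are resampled
#'   to the smallest before alignment.
#' @return A registered [hologram_stack] (common pixel = smallest).
#' @export
prepare_stack <- function(stack, pixels = NULL) {
  stopifnot(inherits(stack, "hologram_stack"))
  imgs <- stack$images
  pixel <- stack$pixel
  if (!is.null(pixels)) {
    if (length(pixels) != length(imgs))
      stop("need one pixel size per image")
    pixel <- min(pixels)
    imgs <- Map(function(m, p) {
      out <- resample_to_pixel(m, p, pixel)
      attr(out, "pixel") <- NULL
      out
    }, imgs, pixels)
    shp <- dim(imgs[[1]])
    imgs <- lapply(imgs, function(m) {
      if (!identical(dim(m), shp))
        m <- m[seq_len(shp[1]), seq_len(shp[2]), drop = FALSE]
      m
    })
  }
  if (length(imgs) > 1) {
    sh <- align_stack(imgs)
    imgs <- lapply(seq_along(imgs), function(i)
      pmax(apply_shift(imgs[[i]], -sh[i, 1], -sh[i, 2]), 0))
  }
  hologram_stack(imgs, stack$distances, pixel, stack$wavelength)
}
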