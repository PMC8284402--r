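# Multi-distance hologram stacks: the common input of all retrieval methods.

#' Multi-distance hologram stack
#'
#' A set of flat/dark-corrected, co-aligned intensity images of the same
#' object recorded at distinct effective propagation distances, normalized so
#' the background is ~1, on a common effective pixel grid.
#'
#' @param images List of non-negative numeric matrices (or a single matrix),
#'   all the same shape.
#' @param distances Effective propagation distance (m) per image; distinct
#'   when more than one image is given.
#' @param pixel Effective pixel size (m).
#' @param wavelength Wavelength (m).
#' @return Object of class `hologram_stack`.
#' @export
hologram_stack <- function(images, distances, pixel, wavelength) {
  if (is.matrix(images)) images <- list(images)
  images <- lapply(images, as.matrix)
  n <- length(images)
  if (n == 0) stop("at least one image required")
  if (length(distances) != n)
    stop("need one distance per image")
  shp <- dim(images[[1]])
  if (!all(vapply(images, function(m) identical(dim(m), shp), logical(1))))
    stop("all images must share shape")
  if (any(vapply(images, function(m) any(m < 0), logical(1))))
    stop("intensities must be non-negative")
  if (n > 1 && anyDuplicated(distances))
    stop("effective distances must be distinct")
  if (pixel <= 0 || wavelength <= 0)
    stop("pixel and wavelength must be positive")
  structure(list(images = images, distances = as.numeric(distances),
                 pixel = pixel, wavelength = wavelength),
            class = "hologram_stack")
}

#' @export
print.hologram_stack <- function(x, ...) {
  cat(sprintf("<hologram_stack> %d image(s) %d x %d, pixel %.4g m\n",
              length(x$images), nrow(x$images[[1]]), ncol(x$images[[1]]),
              x$pixel))
  cat("  effective distances (m):", paste(signif(x$distances, 4),
                                          collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.hologram_stack <- function(x) length(x$images)

#' Normalize a stack to unit background
#'
#' Divides each image by its mean (or by a supplied flat image). The "1"
#' baseline of every linearized retrieval model assumes this normalization.
#'
#' @param stack A [hologram_stack].
#' @param flats Optional list of flat images (one per distance).
#' @return A normalized [hologram_stack].
#' @export
normalize_stack <- function(stack, flats = NULL) {
  stopifnot(inherits(stack, "hologram_stack"))
  imgs <- if (is.null(flats)) {
    lapply(stack$images, function(m) m / mean(m))
  } else {
    if (length(flats) != length(stack$images))
      stop("need one flat per image")
    Map(function(m, fl) m / fl, stack$images, flats)
  }
  hologram_stack(imgs, stack$distances, stack$pixel, stack$wavelength)
}

#' Normalized root-mean-square error
#'
#' RMS difference between an estimate and the ground truth, normalized by the
#' truth's dynamic range. Because the mean phase is unobservable in
#' propagation imaging, the mean difference is removed by default before
#' computing the RMS.
#'
#' @param estimate,truth Numeric matrices of the same shape.
#' @param align_mean Remove the mean difference first (default `TRUE`).
#' @return A single number; 0 means perfect recovery.
#' @export
nrmse <- function(estimate, truth, align_mean = TRUE) {
  stopifnot(identical(dim(estimate), dim(truth)))
  d <- estimate - truth
  if (align_mean) d <- d - mean(d)
  rng <- diff(range(truth))
  if (rng == 0) rng <- 1
  sqrt(mean(d^2)) / rng
}
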