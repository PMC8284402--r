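# On-disk dataset dialect and flat/dark correction.
#
# Layout (TIFF-dir):
#   <root>/meta.json                geometry, z1 per distance, pixel,
#                                   wavelength, counts, seed, shifts, truth?
#   <root>/dist_<k>/proj_<n>.tif    projections (0-based k and n in names)
#   <root>/flats/dist_<k>.tif       optional flat per distance
#   <root>/darks/dist_<k>.tif       optional dark per distance
#   <root>/truth/{phi,B}.tif        ground truth for simulated data
# All images are 32-bit float TIFF. Indices are 0-based half-open ranges.

proj_name <- function(n) sprintf("proj_%05d.tif", n)
dist_dir <- function(k) sprintf("dist_%d", k)

#' Write a simulated dataset (or stack) to a dataset directory
#'
#' @param x A `simulated_dataset` or [hologram_stack].
#' @param path Target directory (created; must not already contain data).
#' @param n_projections Number of projection slots; the same images are
#'   currently written per projection index (single-projection default).
#' @return `path` invisibly.
#' @export
write_dataset <- function(x, path, n_projections = 1) {
  if (inherits(x, "hologram_stack")) {
    x <- list(stack = x, truth = NULL, flats = NULL,
              z1_list = NULL, n0_photons = Inf, seed = NULL)
  }
  stack <- x$stack
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  nd <- length(stack$images)
  for (k in seq_len(nd) - 1L) {
    dir.create(file.path(path, dist_dir(k)), showWarnings = FALSE)
    for (n in seq_len(n_projections) - 1L)
      write_tiff_float(stack$images[[k + 1]],
                       file.path(path, dist_dir(k), proj_name(n)))
  }
  if (!is.null(x$flats)) {
    dir.create(file.path(path, "flats"), showWarnings = FALSE)
    for (k in seq_len(nd) - 1L)
      write_tiff_float(x$flats[[k + 1]],
                       file.path(path, "flats", paste0(dist_dir(k),
                                                       ".tif")))
  }
  if (!is.null(x$truth)) {
    dir.create(file.path(path, "truth"), showWarnings = FALSE)
    write_tiff_float(x$truth$phi, file.path(path, "truth", "phi.tif"))
    write_tiff_float(x$truth$B, file.path(path, "truth", "B.tif"))
  }
  meta <- list(
    layout = "tiff_dir",
    n_projections = n_projections,
    n_distances = nd,
    distances_m = stack$distances,
    z1_m = x$z1_list,
    pixel_m = stack$pixel,
    wavelength_m = stack$wavelength,
    n0_photons = if (is.infinite(x$n0_photons)) "Inf" else x$n0_photons,
    seed = x$seed
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Open a dataset directory
#'
#' @param path Dataset root directory containing `meta.json`.
#' @return Object of class `holo_dataset` with the metadata and lazy image
#'   accessors; see [read_image] and [read_corrected].
#' @export
open_dataset <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop("no meta.json under ", path)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (identical(meta$n0_photons, "Inf")) meta$n0_photons <- Inf
  structure(list(path = path, meta = meta), class = "holo_dataset")
}

#' @export
print.holo_dataset <- function(x, ...) {
  cat(sprintf("<holo_dataset> %s: %d projection(s) x %d distance(s)\n",
              x$path, x$meta$n_projections, x$meta$n_distances))
  invisible(x)
}

check_indices <- function(ds, projection, distance) {
  if (projection < 0 || projection >= ds$meta$n_projections)
    stop("projection index out of range [0, ", ds$meta$n_projections, ")")
  if (distance < 0 || distance >= ds$meta$n_distances)
    stop("distance index out of range [0, ", ds$meta$n_distances, ")")
}

#' Read a raw projection image
#'
#' @param ds A [open_dataset] handle.
#' @param projection,distance 0-based indices.
#' @return Numeric matrix.
#' @export
read_image <- function(ds, projection, distance) {
  stopifnot(inherits(ds, "holo_dataset"))
  check_indices(ds, projection, distance)
  read_tiff(file.path(ds$path, dist_dir(distance), proj_name(projection)))
}

read_aux <- function(ds, kind, distance) {
  f <- file.path(ds$path, kind, paste0(dist_dir(distance), ".tif"))
  if (file.exists(f)) read_tiff(f) else NULL
}

#' Read a flat/dark-corrected projection
#'
#' Applies `(I - dark) / (flat - dark)` where flats/darks exist for the
#' distance; otherwise the raw image is returned unchanged. Negative
#' corrected values are clipped at 0 (their count is attached as the
#' `"clipped"` attribute and warned about).
#'
#' @inheritParams read_image
#' @return Numeric matrix, background ~ 1 when flats are present.
#' @export
read_corrected <- function(ds, projection, distance) {
  img <- read_image(ds, projection, distance)
  flat <- read_aux(ds, "flats", distance)
  dark <- read_aux(ds, "darks", distance)
  correct_image(img, flat, dark)
}

#' Flat/dark correction of a single image
#'
#' @param img Raw image.
#' @param flat,dark Optional flat/dark frames (same shape); `NULL` skips.
#' @return Corrected image `(img - dark) / (flat - dark)`, clipped below at
#'   0 (count in the `"clipped"` attribute).
#' @export
correct_image <- function(img, flat = NULL, dark = NULL) {
  if (is.null(flat) && is.null(dark)) return(img)
  if (is.null(dark)) dark <- array(0, dim(img))
  if (is.null(flat)) flat <- array(1 + 0 * dark, dim(img)) + dark
  denom <- flat - dark
  nbad <- sum(denom <= 0)
  if (nbad > 0)
    stop(sprintf("flat - dark non-positive at %d pixel(s)", nbad))
  out <- (img - dark) / denom
  nclip <- sum(out < 0)
  if (nclip > 0) {
    warning(sprintf("correction clipped %d negative pixel(s)", nclip))
    out <- pmax(out, 0)
  }
  attr(out, "clipped") <- nclip
  out
}

#' Load a dataset as a hologram stack
#'
#' Reads every distance of one projection, applies flat/dark correction,
#' and assembles a [hologram_stack] using the stored geometry metadata.
#'
#' @param ds A `holo_dataset`.
#' @param projection 0-based projection index.
#' @return A [hologram_stack].
#' @export
load_stack <- function(ds, projection = 0) {
  stopifnot(inherits(ds, "holo_dataset"))
  nd <- ds$meta$n_distances
  imgs <- lapply(seq_len(nd) - 1L, function(k) {
    im <- read_corrected(ds, projection, k)
    attr(im, "clipped") <- NULL
    im
  })
  hologram_stack(imgs, ds$meta$distances_m, ds$meta$pixel_m,
                 ds$meta$wavelength_m)
}
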