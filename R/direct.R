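# Direct (single-shot, filter-based) phase retrieval.
#
# All methods operate per Fourier coefficient on background-normalized
# intensities (background ~ 1). The mean phase is unobservable and is set to
# zero. A small floor alpha_min is always added to every denominator to
# protect the exact zeros of the chirp transfer functions.

.alpha_min <- 1e-12

new_retrieval <- function(phi, method, B = NULL, thickness = NULL,
                          params = list(), clipped = 0L) {
  structure(list(phi = phi, B = B, thickness = thickness, method = method,
                 params = params, clipped = clipped),
            class = "phase_retrieval")
}

#' @export
print.phase_retrieval <- function(x, ...) {
  cat(sprintf("<phase_retrieval> method %s, %d x %d\n", x$method,
              nrow(x$phi), ncol(x$phi)))
  cat(sprintf("  phi range [%.4g, %.4g] rad\n", min(x$phi), max(x$phi)))
  if (!is.null(x$B))
    cat(sprintf("  B   range [%.4g, %.4g]\n", min(x$B), max(x$B)))
  if (x$clipped > 0)
    cat(sprintf("  (%d pixel(s) clipped)\n", x$clipped))
  invisible(x)
}

#' Retrieval configuration
#'
#' Bundles the choice of direct algorithm and its parameters, mainly for the
#' command-line interface; every parameter can also be passed directly to the
#' individual retrieval functions.
#'
#' @param method One of `"wtie"`, `"tiehom"`, `"ctf"`, `"ctfpurephase"`,
#'   `"mixed"`.
#' @param delta_beta Homogeneity ratio delta/beta (> 0) for `tiehom` and the
#'   homogeneous prior of `mixed`.
#' @param alpha Regularization parameter (>= 0).
#' @param prior Prior for the mixed approach: `"none"`, `"homogeneous"`,
#'   `"multimaterial"` or `"heterogeneous"`.
#' @param material_thresholds Strictly increasing cut values on `ln I0`
#'   separating materials (multimaterial prior).
#' @param material_delta_beta delta/beta per material; length must be
#'   `length(material_thresholds) + 1`.
#' @param hetero_fn Function mapping the absorption proxy `B = -ln(I0)/2` to
#'   a per-pixel delta/beta (heterogeneous prior).
#' @param n_iter Iteration count for the iterative refiners.
#' @param beta_feedback HIO feedback parameter in (0, 1].
#' @return Object of class `retrieval_config`.
#' @export
retrieval_config <- function(method = c("wtie", "tiehom", "ctf",
                                        "ctfpurephase", "mixed"),
                             delta_beta = NULL, alpha = 1e-8,
                             prior = c("none", "homogeneous",
                                       "multimaterial", "heterogeneous"),
                             material_thresholds = NULL,
                             material_delta_beta = NULL,
                             hetero_fn = NULL, n_iter = 20L,
                             beta_feedback = 0.9) {
  method <- match.arg(method)
  prior <- match.arg(prior)
  if (alpha < 0) stop("alpha must be >= 0")
  if (!is.null(delta_beta) && delta_beta <= 0)
    stop("delta/beta must be positive")
  if (!is.null(material_thresholds)) {
    if (is.unsorted(material_thresholds, strictly = TRUE))
      stop("material thresholds must be strictly increasing")
    if (is.null(material_delta_beta) ||
        length(material_delta_beta) != length(material_thresholds) + 1)
      stop("need length(material_thresholds) + 1 delta/beta values")
  }
  if (beta_feedback <= 0 || beta_feedback > 1)
    stop("beta_feedback must be in (0, 1]")
  structure(list(method = method, delta_beta = delta_beta, alpha = alpha,
                 prior = prior, material_thresholds = material_thresholds,
                 material_delta_beta = material_delta_beta,
                 hetero_fn = hetero_fn, n_iter = as.integer(n_iter),
                 beta_feedback = beta_feedback),
            class = "retrieval_config")
}

# DFT of (I - 1) per image, plus sin/cos chirp grids per distance.
stack_spectra <- function(stack) {
  ny <- nrow(stack$images[[1]]); nx <- ncol(stack$images[[1]])
  chi <- lapply(stack$distances, function(d)
    chirp_phase(ny, nx, stack$pixel, stack$wavelength, d))
  list(
    itilde = lapply(stack$images, function(m) fft2(m - 1)),
    s = lapply(chi, sin),
    c = lapply(chi, cos)
  )
}

#' Weak-object TIE (Bronnikov-type) phase retrieval
#'
#' Single-distance retrieval assuming weak absorption and short propagation:
#' `phi~(f) = DFT[I_D / mean(I_D) - 1] / (2*pi*lambda*D*|f|^2 + alpha)` for
#' `f != 0`, and `phi~(0) = 0` (the mean phase is unobservable).
#'
#' @param stack A [hologram_stack]; the first image/distance is used.
#' @param alpha Regularization (>= 0); stabilizes the low frequencies.
#' @return A `phase_retrieval` with the `phi` map (radians).
#' @export
wtie <- function(stack, alpha = 0) {
  stopifnot(inherits(stack, "hologram_stack"), alpha >= 0)
  d <- stack$distances[1]
  if (d == 0) stop("degenerate distance: WTIE needs D > 0")
  img <- stack$images[[1]]
  ny <- nrow(img); nx <- ncol(img)
  f2 <- freq_squared_grid(ny, nx, stack$pixel)
  denom <- 2 * pi * stack$wavelength * d * f2 + alpha + .alpha_min
  num <- fft2(img / mean(img) - 1)
  phit <- num / denom
  phit[1, 1] <- 0
  new_retrieval(Re(ifft2(phit)), "wtie", params = list(alpha = alpha))
}

#' Homogeneous-object TIE (Paganin-type) phase retrieval
#'
#' Assumes a single material so `phi = -(delta/beta) * B`. With
#' `gamma = delta/beta` and filter `g_D(f) = 1 + pi*lambda*D*gamma*|f|^2`:
#' one distance gives `A = IDFT[DFT(I_D) / g_D]`; several distances give the
#' regularized least-squares combination
#' `DFT(A) = sum_D g_D DFT(I_D) / (sum_D g_D^2 + alpha)`. Then
#' `B = -ln(A)/2`, `phi = gamma*ln(A)/2` and, if `beta` is supplied, the
#' projected thickness `t = B*lambda / (2*pi*beta)`.
#'
#' Non-positive `A` pixels are clipped at `1e-8`; the count is reported in
#' the result and as a warning.
#'
#' @param stack A [hologram_stack].
#' @param delta_beta Homogeneity ratio delta/beta (> 0).
#' @param alpha Regularization for the multi-distance combination.
#' @param beta Optional absorption index beta, to convert `B` to thickness.
#' @return A `phase_retrieval` with `phi`, `B` and (optionally) `thickness`.
#' @export
tiehom <- function(stack, delta_beta, alpha = 0, beta = NULL) {
  stopifnot(inherits(stack, "hologram_stack"), delta_beta > 0, alpha >= 0)
  ny <- nrow(stack$images[[1]]); nx <- ncol(stack$images[[1]])
  f2 <- freq_squared_grid(ny, nx, stack$pixel)
  g <- lapply(stack$distances, function(d)
    1 + pi * stack$wavelength * d * delta_beta * f2)
  if (length(stack) == 1) {
    ahat <- fft2(stack$images[[1]]) / g[[1]]
  } else {
    num <- Reduce(`+`, Map(function(gd, m) gd * fft2(m), g, stack$images))
    den <- Reduce(`+`, lapply(g, function(gd) gd^2)) + alpha + .alpha_min
    ahat <- num / den
  }
  a <- Re(ifft2(ahat))
  clipped <- sum(a <= 0)
  if (clipped > 0) {
    warning(sprintf("tiehom: %d non-positive pixel(s) clipped", clipped))
    a <- pmax(a, 1e-8)
  }
  lg <- log(a)
  b <- -lg / 2
  thickness <- if (!is.null(beta))
    b * stack$wavelength / (2 * pi * beta) else NULL
  new_retrieval(delta_beta * lg / 2, "tiehom", B = b, thickness = thickness,
                params = list(delta_beta = delta_beta, alpha = alpha),
                clipped = as.integer(clipped))
}

#' Multi-distance CTF phase and attenuation retrieval
#'
#' Per-frequency Tikhonov-regularized least squares of the weak-object CTF
#' model over all distances. With `s_D = sin(chi_D)`, `c_D = cos(chi_D)` and
#' `I~'_D = DFT[I_D - 1]`, the 2x2 normal equations
#' \deqn{[4\sum s^2 + \alpha, -4\sum sc; -4\sum sc, 4\sum c^2 + \alpha]
#'       (\tilde\phi, \tilde B)^T =
#'       (2\sum s_D \tilde I'_D, -2\sum c_D \tilde I'_D)^T}
#' are solved element-wise; `phi~(0)` is set to 0 and `B~(0)` follows from
#' the mean attenuation.
#'
#' @param stack A [hologram_stack]; two or more distances make the two-map
#'   solve well posed (one is accepted; `alpha` damps the null directions).
#' @param alpha Regularization added to the normal-equation diagonal.
#' @return A `phase_retrieval` with `phi` and `B` maps.
#' @export
ctf_retrieve <- function(stack, alpha = 1e-8) {
  stopifnot(inherits(stack, "hologram_stack"), alpha >= 0)
  sp <- stack_spectra(stack)
  a <- alpha + .alpha_min
  a11 <- Reduce(`+`, lapply(sp$s, function(s) 4 * s^2)) + a
  a22 <- Reduce(`+`, lapply(sp$c, function(c) 4 * c^2)) + a
  a12 <- -Reduce(`+`, Map(function(s, c) 4 * s * c, sp$s, sp$c))
  b1 <- Reduce(`+`, Map(function(s, it) 2 * s * it, sp$s, sp$itilde))
  b2 <- -Reduce(`+`, Map(function(c, it) 2 * c * it, sp$c, sp$itilde))
  det <- a11 * a22 - a12^2
  phit <- (a22 * b1 - a12 * b2) / det
  bt <- (a11 * b2 - a12 * b1) / det
  phit[1, 1] <- 0
  new_retrieval(Re(ifft2(phit)), "ctf", B = Re(ifft2(bt)),
                params = list(alpha = alpha))
}

#' Pure-phase CTF retrieval
#'
#' The absorption-free reduction of [ctf_retrieve]:
#' `phi~ = sum_D 2 s_D I~'_D / (sum_D 4 s_D^2 + alpha)`, `phi~(0) = 0`.
#'
#' @inheritParams ctf_retrieve
#' @return A `phase_retrieval` with the `phi` map.
#' @export
ctf_pure_phase <- function(stack, alpha = 1e-8) {
  stopifnot(inherits(stack, "hologram_stack"), alpha >= 0)
  sp <- stack_spectra(stack)
  num <- Reduce(`+`, Map(function(s, it) 2 * s * it, sp$s, sp$itilde))
  den <- Reduce(`+`, lapply(sp$s, function(s) 4 * s^2)) + alpha + .alpha_min
  phit <- num / den
  phit[1, 1] <- 0
  new_retrieval(Re(ifft2(phit)), "ctfpurephase",
                params = list(alpha = alpha))
}

# Per-pixel delta/beta map for the mixed-approach priors.
prior_delta_beta <- function(prior, log_i0, cfg) {
  switch(prior,
    homogeneous = {
      if (is.null(cfg$delta_beta))
        stop("homogeneous prior needs delta_beta")
      array(cfg$delta_beta, dim(log_i0))
    },
    multimaterial = {
      if (is.null(cfg$material_thresholds) ||
          is.null(cfg$material_delta_beta) ||
          length(cfg$material_delta_beta) !=
            length(cfg$material_thresholds) + 1)
        stop("multimaterial prior needs thresholds and matching delta/beta")
      idx <- findInterval(log_i0, cfg$material_thresholds) + 1L
      array(cfg$material_delta_beta[idx], dim(log_i0))
    },
    heterogeneous = {
      if (!is.function(cfg$hetero_fn))
        stop("heterogeneous prior needs hetero_fn")
      g <- cfg$hetero_fn(-log_i0 / 2)
      if (length(g) == 1) g <- array(g, dim(log_i0))
      array(g, dim(log_i0))
    },
    stop("unknown prior")
  )
}

#' Mixed TIE/CTF phase retrieval with object priors
#'
#' Combines the validity domains of the CTF and the TIE: it tolerates strong
#' attenuation (via a measured contact image `I0`) and long distances, for
#' slowly varying objects. It solves for `psi = I0 * phi` in Fourier space
#' from `Delta~_D = DFT[I_D] - cos(chi_D) DFT[I0]`:
#' `psi~ = (sum_D 2 s_D Delta~_D + alpha * DFT[psi_prior]) /
#'         (sum_D 4 s_D^2 + alpha)`, then `phi = IDFT[psi~] / I0`.
#'
#' The prior regularizes the poorly transferred low frequencies:
#' `"none"` uses `psi_prior = 0`; `"homogeneous"` uses
#' `phi_prior = (delta/beta)/2 * ln I0`; `"multimaterial"` selects a
#' per-pixel delta/beta by thresholding `ln I0`; `"heterogeneous"` maps the
#' absorption proxy `B = -ln(I0)/2` through a caller-supplied function.
#'
#' @param stack A [hologram_stack] of propagated images (D > 0).
#' @param contact_image Contact-plane (attenuation) intensity `I0`, same
#'   shape as the stack images; strictly positive (non-positive pixels are
#'   clipped at `1e-8` with a warning).
#' @param prior Prior type (see Details).
#' @param delta_beta,material_thresholds,material_delta_beta,hetero_fn
#'   Prior parameters, as in [retrieval_config].
#' @param alpha Regularization weight coupling data and prior.
#' @return A `phase_retrieval` with the `phi` map.
#' @export
mixed_approach <- function(stack, contact_image,
                           prior = c("none", "homogeneous", "multimaterial",
                                     "heterogeneous"),
                           delta_beta = NULL, material_thresholds = NULL,
                           material_delta_beta = NULL, hetero_fn = NULL,
                           alpha = 1e-8) {
  stopifnot(inherits(stack, "hologram_stack"), alpha >= 0)
  prior <- match.arg(prior)
  if (missing(contact_image) || is.null(contact_image))
    stop("mixed_approach requires a contact (attenuation) image")
  i0 <- as.matrix(contact_image)
  if (!identical(dim(i0), dim(stack$images[[1]])))
    stop("contact image shape must match the stack")
  clipped <- sum(i0 <= 0)
  if (clipped > 0) {
    warning(sprintf("mixed_approach: %d non-positive I0 pixel(s) clipped",
                    clipped))
    i0 <- pmax(i0, 1e-8)
  }
  sp <- stack_spectra(stack)
  i0hat <- fft2(i0)
  ny <- nrow(i0); nx <- ncol(i0)
  chi <- lapply(stack$distances, function(d)
    chirp_phase(ny, nx, stack$pixel, stack$wavelength, d))
  delta_hat <- Map(function(m, ch) fft2(m) - cos(ch) * i0hat,
                   stack$images, chi)
  num <- Reduce(`+`, Map(function(ch, dh) 2 * sin(ch) * dh, chi, delta_hat))
  if (prior != "none") {
    gmap <- prior_delta_beta(prior, log(i0),
                             list(delta_beta = delta_beta,
                                  material_thresholds = material_thresholds,
                                  material_delta_beta = material_delta_beta,
                                  hetero_fn = hetero_fn))
    psi_prior <- i0 * (gmap / 2) * log(i0)
    num <- num + alpha * fft2(psi_prior)
  }
  den <- Reduce(`+`, lapply(chi, function(ch) 4 * sin(ch)^2)) +
    alpha + .alpha_min
  psi <- Re(ifft2(num / den))
  new_retrieval(psi / i0, "mixed",
                params = list(alpha = alpha, prior = prior,
                              delta_beta = delta_beta),
                clipped = as.integer(clipped))
}

#' Dispatch a direct retrieval from a configuration
#'
#' @param stack A [hologram_stack].
#' @param config A [retrieval_config].
#' @param contact_image Contact image, required for `method = "mixed"`.
#' @return A `phase_retrieval`.
#' @export
retrieve_phase <- function(stack, config, contact_image = NULL) {
  stopifnot(inherits(config, "retrieval_config"))
  switch(config$method,
    wtie = wtie(stack, alpha = config$alpha),
    tiehom = {
      if (is.null(config$delta_beta)) stop("tiehom needs delta_beta")
      tiehom(stack, config$delta_beta, alpha = config$alpha)
    },
    ctf = ctf_retrieve(stack, alpha = config$alpha),
    ctfpurephase = ctf_pure_phase(stack, alpha = config$alpha),
    mixed = mixed_approach(stack, contact_image, prior = config$prior,
                           delta_beta = config$delta_beta,
                           material_thresholds = config$material_thresholds,
                           material_delta_beta = config$material_delta_beta,
                           hetero_fn = config$hetero_fn,
                           alpha = config$alpha)
  )
}
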