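# Iterative refinement of a retrieved wave: steepest descent on the
# intensity misfit, and hybrid input-output / error-reduction projections.
#
# The iterate is the full complex object wave u (not the phase alone); the
# phase map is arg(u). Both schemes should be initialized from a direct
# method: starting from flat or random fields generally stalls in poor local
# optima, except in simple supported cases.

#' Object-domain constraints for HIO/ER
#'
#' @param support Logical matrix, `TRUE` where the object may differ from
#'   the background (unit transmission); `NULL` means no support constraint.
#' @param nonnegativity Enforce a non-negative absorption exponent, i.e.
#'   `|u| <= 1`.
#' @param beta_feedback HIO feedback parameter in (0, 1], default 0.9.
#' @return Object of class `iter_constraints`.
#' @export
iter_constraints <- function(support = NULL, nonnegativity = FALSE,
                             beta_feedback = 0.9) {
  if (!is.null(support)) {
    support <- as.matrix(support)
    if (!is.logical(support)) stop("support must be a logical mask")
  }
  if (beta_feedback <= 0 || beta_feedback > 1)
    stop("beta_feedback must be in (0, 1]")
  structure(list(support = support, nonnegativity = isTRUE(nonnegativity),
                 beta_feedback = beta_feedback),
            class = "iter_constraints")
}

new_iterative_state <- function(u, history, what) {
  structure(list(u = u, history = history, iterations = length(history) - 1L,
                 objective = what),
            class = "iterative_state")
}

#' @export
print.iterative_state <- function(x, ...) {
  cat(sprintf("<iterative_state> %d iteration(s), %s %.6g -> %.6g\n",
              x$iterations, x$objective, x$history[1],
              x$history[length(x$history)]))
  invisible(x)
}

#' Intensity misfit of a wave estimate
#'
#' `C(u) = sum_D sum_pixels (|P_D u|^2 - I_D)^2` where `P_D` is Fresnel
#' propagation to effective distance D.
#'
#' @param u A [wavefield] estimate of the object exit wave.
#' @param stack A [hologram_stack] of measured intensities.
#' @return A single non-negative number.
#' @export
misfit <- function(u, stack) {
  stopifnot(inherits(u, "wavefield"), inherits(stack, "hologram_stack"))
  if (!identical(dim(u$values), dim(stack$images[[1]])))
    stop("shape mismatch between wave and stack")
  s <- 0
  for (k in seq_along(stack$images)) {
    ud <- fresnel_propagate(u, stack$wavelength, stack$distances[k])
    s <- s + sum((intensity(ud) - stack$images[[k]])^2)
  }
  s
}

#' Gradient of the intensity misfit
#'
#' Wirtinger gradient with respect to the conjugate wave:
#' `grad C = sum_D 4 * P_{-D}[ (|u_D|^2 - I_D) * u_D ]` with
#' `u_D = P_D u`. A steepest-descent step is `u - step * grad`.
#'
#' @inheritParams misfit
#' @return Complex matrix of the same shape as `u$values`.
#' @export
misfit_gradient <- function(u, stack) {
  stopifnot(inherits(u, "wavefield"), inherits(stack, "hologram_stack"))
  g <- matrix(0 + 0i, nrow(u$values), ncol(u$values))
  for (k in seq_along(stack$images)) {
    d <- stack$distances[k]
    ud <- fresnel_propagate(u, stack$wavelength, d)
    resid <- (intensity(ud) - stack$images[[k]]) * ud$values
    back <- fresnel_propagate(wavefield(resid, u$pixel),
                              stack$wavelength, -d)
    g <- g + 4 * back$values
  }
  g
}

#' Steepest descent on the intensity misfit
#'
#' Gradient descent with Armijo backtracking (step halving), so the misfit
#' history is non-increasing by construction. Initialize from a direct
#' method (e.g. the CTF estimate converted with [as_wavefield]).
#'
#' @param init Initial [wavefield].
#' @param stack A [hologram_stack].
#' @param n_iter Number of iterations (>= 0).
#' @param step0 Initial step; default `1 / (8 * sum_D max(I_D))`.
#' @param armijo_c Sufficient-decrease constant (default 1e-4).
#' @param max_halvings Maximum step halvings per iteration; if no decrease
#'   is found the iterate is kept and descent stops early.
#' @return An `iterative_state` with the final wave and the cost history
#'   (length `n_iter_done + 1`).
#' @export
gradient_descent <- function(init, stack, n_iter = 20, step0 = NULL,
                             armijo_c = 1e-4, max_halvings = 40) {
  stopifnot(inherits(init, "wavefield"), inherits(stack, "hologram_stack"),
            n_iter >= 0)
  if (is.null(step0))
    step0 <- 1 / (8 * sum(vapply(stack$images, max, numeric(1))))
  u <- init
  cost <- misfit(u, stack)
  if (!is.finite(cost)) stop("divergent at iteration 0: non-finite misfit")
  history <- cost
  for (it in seq_len(n_iter)) {
    g <- misfit_gradient(u, stack)
    gnorm2 <- sum(Mod(g)^2)
    if (gnorm2 == 0) break
    step <- step0
    accepted <- FALSE
    for (h in seq_len(max_halvings)) {
      trial <- wavefield(u$values - step * g, u$pixel)
      ctrial <- misfit(trial, stack)
      if (!is.finite(ctrial))
        stop(sprintf("divergence at iteration %d: non-finite misfit", it))
      if (ctrial <= cost - armijo_c * step * gnorm2) {
        u <- trial; cost <- ctrial; accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break  # no descent direction progress at machine scale
    history <- c(history, cost)
  }
  new_iterative_state(u, history, "misfit")
}

# Replace the modulus of the propagated wave by the measured sqrt(I),
# keeping the phase; back-propagate to the object plane.
magnitude_projection <- function(u, stack, k) {
  d <- stack$distances[k]
  ud <- fresnel_propagate(u, stack$wavelength, d)
  m <- Mod(ud$values)
  ph <- ifelse(m > 0, ud$values / m, 1 + 0i)
  udp <- sqrt(stack$images[[k]]) * ph
  fresnel_propagate(wavefield(udp, u$pixel), stack$wavelength, -d)
}

constraint_violation <- function(v, cons) {
  viol <- matrix(FALSE, nrow(v), ncol(v))
  if (!is.null(cons$support)) viol <- viol | !cons$support
  if (cons$nonnegativity) viol <- viol | (Mod(v) > 1)
  viol
}

apply_constraints_er <- function(v, cons) {
  if (!is.null(cons$support)) v[!cons$support] <- 1 + 0i
  if (cons$nonnegativity) {
    m <- Mod(v)
    over <- m > 1
    v[over] <- v[over] / m[over]
  }
  v
}

#' Parse an iteration schedule string
#'
#' `"45:hio,5:er"` becomes `list(list(mode = "hio", count = 45),
#' list(mode = "er", count = 5))`.
#'
#' @param x Schedule string.
#' @return List of `(mode, count)` stages.
#' @export
iteration_schedule <- function(x) {
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  lapply(parts, function(p) {
    kv <- strsplit(trimws(p), ":", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("schedule stages must look like '45:hio'")
    mode <- tolower(kv[2])
    if (!mode %in% c("hio", "er")) stop("schedule mode must be hio or er")
    list(mode = mode, count = as.integer(kv[1]))
  })
}

#' Hybrid input-output / error-reduction iterations
#'
#' Alternating projections between the measured moduli and the object-domain
#' constraints (support, non-negativity). Each iteration visits the
#' distances cyclically: propagate, replace the modulus by `sqrt(I_D)`
#' keeping the phase, back-propagate, then apply the object update. ER
#' resets every pixel to the constrained value (outside the support the
#' background `1 + 0i`); HIO keeps the projection where the constraints
#' hold and applies the feedback `u - beta_fb * u'` where they are violated.
#'
#' The recorded history is the detector-plane residual
#' `sum_D || |u_D| - sqrt(I_D) ||^2`, non-increasing for pure ER (it is an
#' alternating projection) but not necessarily for HIO.
#'
#' @param init Initial [wavefield].
#' @param stack A [hologram_stack].
#' @param constraints An [iter_constraints].
#' @param schedule List of stages `list(mode, count)` (see
#'   [iteration_schedule]); default 45 HIO then 5 ER.
#' @return An `iterative_state` with the final wave and residual history.
#' @export
hio_er <- function(init, stack,
                   constraints = iter_constraints(),
                   schedule = list(list(mode = "hio", count = 45),
                                   list(mode = "er", count = 5))) {
  stopifnot(inherits(init, "wavefield"), inherits(stack, "hologram_stack"),
            inherits(constraints, "iter_constraints"))
  if (any(vapply(stack$images, function(m) any(m < 0), logical(1))))
    stop("negative intensities: correct the data upstream")
  u <- init
  history <- detector_residual(u, stack)
  for (stage in schedule) {
    for (it in seq_len(stage$count)) {
      for (k in seq_along(stack$images)) {
        up <- magnitude_projection(u, stack, k)
        if (stage$mode == "er") {
          u <- wavefield(apply_constraints_er(up$values, constraints),
                         u$pixel)
        } else {
          v <- up$values
          viol <- constraint_violation(v, constraints)
          proj <- apply_constraints_er(v, constraints)
          newv <- v
          # feedback toward the feasible point; with a zero background this
          # reduces to the classical u - beta * u' update
          newv[viol] <- u$values[viol] -
            constraints$beta_feedback * (v[viol] - proj[viol])
          u <- wavefield(newv, u$pixel)
        }
      }
      history <- c(history, detector_residual(u, stack))
    }
  }
  new_iterative_state(u, history, "residual")
}

# sum_D || |P_D u| - sqrt(I_D) ||^2
detector_residual <- function(u, stack) {
  s <- 0
  for (k in seq_along(stack$images)) {
    ud <- fresnel_propagate(u, stack$wavelength, stack$distances[k])
    s <- s + sum((Mod(ud$values) - sqrt(stack$images[[k]]))^2)
  }
  s
}

#' Per-distance HIO/ER averaging driver
#'
#' Convenience reading of the "average of five cycles of 45 HIO + 5 ER per
#' acquired image" recipe: within each cycle the schedule is run
#' independently on every single-distance sub-stack starting from the
#' current estimate, the resulting waves are averaged, and the average seeds
#' the next cycle.
#'
#' @inheritParams hio_er
#' @param n_cycles Number of outer cycles (default 5).
#' @return An `iterative_state`; the history is the detector residual of the
#'   averaged wave after each cycle.
#' @export
hio_er_per_distance <- function(init, stack,
                                constraints = iter_constraints(),
                                schedule = list(list(mode = "hio",
                                                     count = 45),
                                                list(mode = "er",
                                                     count = 5)),
                                n_cycles = 5) {
  stopifnot(inherits(init, "wavefield"))
  u <- init
  history <- detector_residual(u, stack)
  for (cy in seq_len(n_cycles)) {
    waves <- lapply(seq_along(stack$images), function(k) {
      sub <- hologram_stack(stack$images[k], stack$distances[k],
                            stack$pixel, stack$wavelength)
      hio_er(u, sub, constraints, schedule)$u$values
    })
    u <- wavefield(Reduce(`+`, waves) / length(waves), u$pixel)
    history <- c(history, detector_residual(u, stack))
  }
  new_iterative_state(u, history, "residual")
}
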