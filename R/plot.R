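# Quick-look display helpers (base graphics); diagnostics only.

#' Display an image matrix in detector orientation
#'
#' @param x Numeric matrix (row = y, column = x).
#' @param main Plot title.
#' @param ... Passed to [graphics::image].
#' @return Invisibly, `x`.
#' @export
plot_image <- function(x, main = NULL, ...) {
  ny <- nrow(x)
  graphics::image(t(x[ny:1, , drop = FALSE]), col = grDevices::gray.colors(256),
                  axes = FALSE, asp = ny / ncol(x), main = main, ...)
  invisible(x)
}

#' @export
plot.wavefield <- function(x, what = c("phase", "intensity"), ...) {
  what <- match.arg(what)
  m <- if (what == "phase") Arg(x$values) else intensity(x)
  plot_image(m, main = paste("wavefield", what), ...)
}

#' @export
plot.phase_retrieval <- function(x, ...) {
  plot_image(x$phi, main = paste("retrieved phase:", x$method), ...)
}

#' @export
plot.iterative_state <- function(x, ...) {
  graphics::plot(seq_along(x$history) - 1, x$history, type = "b",
                 xlab = "iteration", ylab = x$objective, log = "y", ...)
  invisible(x)
}
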