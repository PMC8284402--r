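# Parallel mapping over projection indices. Projections in a tomographic
# scan are independent, so the loop is embarrassingly parallel; the process
# backend forks workers (base `parallel`), falling back to serial where
# forking is unavailable (Windows).

#' Map a function over projection indices, serially or in parallel
#'
#' `fn` must be pure per projection; the process backend is then bit-exact
#' identical to the serial map, order preserved. Worker errors are
#' re-raised naming the failing projection index.
#'
#' @param fn Function of one projection index.
#' @param projections Integer vector of projection indices (typically a
#'   0-based half-open range, e.g. `seq_len(n) - 1`); may be empty.
#' @param backend `"serial"` or `"process"`.
#' @param n_workers Worker count for the process backend.
#' @return List of results, in the order of `projections`.
#' @export
parallel_map <- function(fn, projections, backend = c("serial", "process"),
                         n_workers = 2L) {
  backend <- match.arg(backend)
  if (length(projections) == 0) return(list())
  wrapped <- function(p) {
    tryCatch(list(ok = TRUE, value = fn(p)),
             error = function(e)
               list(ok = FALSE, value = conditionMessage(e)))
  }
  res <- if (backend == "serial" || .Platform$OS.type == "windows") {
    lapply(projections, wrapped)
  } else {
    parallel::mclapply(projections, wrapped,
                       mc.cores = max(1L, as.integer(n_workers)),
                       mc.preschedule = TRUE)
  }
  bad <- which(!vapply(res, function(r) isTRUE(r$ok), logical(1)))
  if (length(bad) > 0)
    stop(sprintf("projection %s failed: %s", projections[bad[1]],
                 res[[bad[1]]]$value))
  lapply(res, `[[`, "value")
}
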