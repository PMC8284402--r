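# Flat key = value configuration files. Every CLI flag has a config twin;
# CLI values override the file. Lines starting with '#' are comments.
#
# Recognized keys (all optional unless a command requires them):
#   energy_kev, z1_m, zd_m, pixel_m        acquisition geometry
#   method, delta_beta, alpha, prior       retrieval
#   material_thresholds, material_delta_beta  (comma-separated lists)
#   n_iter, beta_feedback, schedule        iterative refinement
#   n0_photons, seed, distances_m          simulation (comma-separated)
#   phantom, shape, radius_px, t_max_m, delta, beta, n_spokes, edge_sigma
#   backend, n_workers                     parallelism

#' Read a flat key/value configuration file
#'
#' @param path Path to the config file.
#' @return Named list; values are converted to numeric vectors where every
#'   comma-separated element parses as a number, otherwise kept as strings.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed config line (need key = value): ", ln)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(nums)) nums else val
  }
  out
}
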