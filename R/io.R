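# CSV/JSON writers and readers; CSV carries full double precision (17
# significant digits) so write/read round-trips are bit-stable.

fmt_full <- function(x) formatC(x, digits = 17, format = "g")

#' Write / read a trajectory
#'
#' The CSV has header `t,x,y,z` (or `t,s0..s{m-1}` for other dimensions) at
#' full double precision; a JSON sidecar (`<path>.json`) stores the scheme,
#' step, parameters, and initial time so the object round-trips exactly.
#'
#' @param traj a `trajectory` object.
#' @param path CSV file path.
#' @param seed optional seed recorded in the sidecar for provenance.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, seed = NULL) {
  df <- data.frame(t = fmt_full(trajectory_times(traj)))
  for (j in seq_len(ncol(traj$states))) {
    df[[colnames(traj$states)[j]]] <- fmt_full(traj$states[, j])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(t0 = traj$t0, h = traj$h,
               scheme = unclass(traj$scheme)[c("name", "order", "tol", "max_iter")],
               params = if (is.null(traj$params)) NULL else unclass(traj$params),
               seed = seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  states <- as.matrix(df[, -1, drop = FALSE])
  scheme <- scheme_spec(meta$scheme$name, tol = meta$scheme$tol,
                        max_iter = meta$scheme$max_iter)
  params <- meta$params
  if (!is.null(params) && all(c("sigma", "rho", "beta") %in% names(params))) {
    params <- lorenz_params(params$sigma, params$rho, params$beta)
  }
  structure(list(t0 = meta$t0, h = meta$h, states = states,
                 scheme = scheme, params = params),
            class = "trajectory")
}

#' Write / read a peak sequence
#'
#' CSV with header `n,t_n,z_n` at full precision.
#'
#' @param peaks a `peak_sequence` object.
#' @param path CSV file path.
#' @return `path` invisibly; `read_peaks` returns a `peak_sequence`.
#' @export
write_peaks <- function(peaks, path) {
  df <- data.frame(n = seq_along(peaks$heights) - 1L,
                   t_n = fmt_full(peaks$times),
                   z_n = fmt_full(peaks$heights))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  df <- utils::read.csv(path)
  peak_sequence(times = df$t_n, heights = df$z_n)
}

#' Write a Lyapunov spectrum as JSON
#'
#' @param spec a `lyapunov_spectrum` object.
#' @param path output file.
#' @param seed optional provenance seed.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path, seed = NULL) {
  jsonlite::write_json(
    list(exponents = spec$exponents, units = spec$units, h = spec$h,
         n_steps = spec$n_steps, burn_in = spec$burn_in, seed = seed),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a regime report (or any report list) as JSON
#'
#' @param report a named list.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}
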