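#' Bifurcation sweep of the Lorenz peak map over rho
#'
#' For each value of `rho` the Lorenz flow is integrated (RK4, `h = 0.01`
#' by default), an initial transient is discarded, and the next `n_peaks`
#' peak heights of the scanned coordinate are recorded. Plotted as
#' `rho` vs peak height this is the classical bifurcation diagram: single-
#' or few-peak columns mark equilibria and periodic windows, wide bands mark
#' chaos. Integration failures at individual grid points are recorded and
#' the sweep continues.
#'
#' @param rho_grid non-empty numeric grid of rho values.
#' @param h integration step.
#' @param sigma,beta remaining Lorenz parameters.
#' @param x0 initial state.
#' @param burn_in_time transient time discarded before recording.
#' @param n_peaks number of post-transient peaks kept per rho.
#' @param record_time time window scanned for peaks after burn-in.
#' @param coord scanned coordinate (`"z"` by default, `"x"` also standard).
#' @param scheme integration scheme.
#' @return a data.frame with columns `param`, `peak` (long format); the
#'   attribute `"failures"` lists grid points whose integration failed.
#' @export
rho_sweep <- function(rho_grid, h = 0.01, sigma = 10, beta = 8 / 3,
                      x0 = c(1, 1, 1), burn_in_time = 30, n_peaks = 100,
                      record_time = 100, coord = "z", scheme = "rk4") {
  if (length(rho_grid) == 0L) pk_stop("empty rho grid", "peaknet_invalid")
  out <- vector("list", length(rho_grid))
  failures <- list()
  n_steps <- ceiling((burn_in_time + record_time) / h)
  burn_steps <- ceiling(burn_in_time / h)
  for (i in seq_along(rho_grid)) {
    rho <- rho_grid[i]
    res <- tryCatch({
      p <- lorenz_params(sigma = sigma, rho = rho, beta = beta)
      tr <- integrate_system(x0, function(s) lorenz_field(s, p), h, n_steps,
                             scheme = scheme, params = p)
      tr$states <- tr$states[-seq_len(burn_steps), , drop = FALSE]
      tr$t0 <- tr$t0 + burn_steps * h
      pk <- detect_peaks(tr, coord = coord)
      utils::head(pk$heights, n_peaks)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[as.character(rho)]] <- conditionMessage(res)
      next
    }
    if (length(res)) out[[i]] <- data.frame(param = rho, peak = res)
  }
  df <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(df)) df <- data.frame(param = numeric(0), peak = numeric(0))
  attr(df, "failures") <- failures
  df
}
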