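#' Synthetic fixtures for oracle-driven tests
#'
#' Deterministic generators (pure functions of their spec, RNG seeded
#' internally) for the datasets the test-suite oracles are built on:
#' * `logistic_orbit` — post-transient heights and successor pairs of a
#'   logistic map (params: `r`, `x0`, `burn_in`);
#' * `lorenz_short` — a short Lorenz trajectory (params: `sigma`, `rho`,
#'   `beta`, `h`, `x0`, `scheme`);
#' * `binary_blocks` — an activity matrix tiled from a given binary block
#'   (params: `block`, a matrix tiled in time);
#' * `planted_cycle` — a peak-height sequence cycling through given values
#'   with optional Gaussian jitter (params: `cycle`, `jitter`).
#'
#' @param kind fixture kind.
#' @param params named list of kind-specific parameters.
#' @param length number of samples / steps / rows generated.
#' @param seed RNG seed (jitter and any random choices).
#' @param dir optional directory: when given, the fixture is also written
#'   as CSV plus a JSON manifest, byte-identical across calls with the
#'   same spec.
#' @return the fixture object (vector, data.frame, matrix, or
#'   `trajectory`), invisibly carrying attribute `"files"` when written.
#' @export
generate_fixture <- function(kind = c("logistic_orbit", "lorenz_short",
                                      "binary_blocks", "planted_cycle"),
                             params = list(), length = 100L, seed = 1L,
                             dir = NULL) {
  kind <- match.arg(kind)
  set.seed(seed)
  obj <- switch(kind,
    logistic_orbit = {
      r <- params$r %||% 3.2
      x0 <- params$x0 %||% 0.2
      burn_in <- params$burn_in %||% 500L
      heights <- iterate_map(logistic_map(r), x0, length, burn_in = burn_in)
      heights
    },
    lorenz_short = {
      if (length > 1e5) pk_stop("lorenz_short capped at 1e5 steps", "peaknet_invalid")
      p <- lorenz_params(params$sigma %||% 10, params$rho %||% 28,
                         params$beta %||% (8 / 3))
      integrate_system(params$x0 %||% c(1, 1, 1),
                       function(s) lorenz_field(s, p),
                       h = params$h %||% 0.01, n_steps = length,
                       scheme = params$scheme %||% "rk4", params = p)
    },
    binary_blocks = {
      block <- params$block
      if (is.null(block)) pk_stop("binary_blocks needs params$block", "peaknet_invalid")
      block <- as.matrix(block)
      reps <- ceiling(length / nrow(block))
      out <- do.call(rbind, rep(list(block), reps))[seq_len(length), , drop = FALSE]
      storage.mode(out) <- "integer"
      out
    },
    planted_cycle = {
      cyc <- params$cycle
      if (is.null(cyc)) pk_stop("planted_cycle needs params$cycle", "peaknet_invalid")
      jitter <- params$jitter %||% 0
      rep_len(cyc, length) + stats::rnorm(length, sd = jitter)
    })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    data_path <- file.path(dir, paste0(kind, ".csv"))
    if (inherits(obj, "trajectory")) {
      write_trajectory(obj, data_path, seed = seed)
    } else if (is.matrix(obj)) {
      utils::write.csv(obj, data_path, row.names = FALSE, quote = FALSE)
    } else {
      utils::write.csv(data.frame(value = fmt_full(obj)), data_path,
                       row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(list(kind = kind, params = params, length = length,
                              seed = seed),
                         file.path(dir, paste0(kind, ".json")),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    attr(obj, "files") <- c(data_path, file.path(dir, paste0(kind, ".json")))
  }
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a
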