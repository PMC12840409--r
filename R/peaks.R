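#' Peak (vertex) sequence
#'
#' Successive strict local maxima of one scanned coordinate of a sampled
#' orbit: times `t_n` (strictly increasing) and heights `z_n`.
#'
#' @param times strictly increasing numeric vector.
#' @param heights numeric vector, same length.
#' @param coord name of the scanned coordinate.
#' @param degenerate logical vector flagging plateau-degenerate peaks.
#' @return an object of class `peak_sequence`.
#' @export
peak_sequence <- function(times, heights, coord = "z",
                          degenerate = logical(length(heights))) {
  if (length(times) != length(heights)) {
    pk_stop("times and heights must have equal length", "peaknet_invalid")
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    pk_stop("peak times must be strictly increasing", "peaknet_invalid")
  }
  structure(list(times = times, heights = heights, coord = coord,
                 degenerate = degenerate),
            class = "peak_sequence")
}

#' @export
print.peak_sequence <- function(x, ...) {
  cat(sprintf("Peak sequence: %d peaks of coordinate '%s'", length(x$heights), x$coord))
  if (any(x$degenerate)) cat(sprintf(" (%d plateau-degenerate)", sum(x$degenerate)))
  cat("\n")
  invisible(x)
}

#' Detect local maxima of a sampled series
#'
#' Interior samples with `s[k-1] < s[k] >= s[k+1]` are peak candidates. Each
#' candidate is refined by the parabola through its three neighbouring
#' samples, giving an interpolated `(t, height)` pair; the interpolation is
#' exact for parabolic data and, for smooth flows, the refined heights
#' converge at the integrator's order. Plateaus of more than two equal
#' samples are returned unrefined and flagged degenerate. Set
#' `refine = FALSE` for series produced by genuine discrete maps, where
#' interpolation between iterates has no meaning.
#'
#' @param x a `trajectory` object or a numeric series.
#' @param coord coordinate name or index to scan (trajectory method).
#' @param refine refine peaks by 3-point quadratic interpolation.
#' @param ... passed between methods.
#' @return a [peak_sequence()].
#' @examples
#' t <- seq(0, 20, by = 0.01)
#' pk <- detect_peaks(sin(t), t = t)
#' diff(pk$times)  # ~ 2*pi apart
#' @export
detect_peaks <- function(x, ...) UseMethod("detect_peaks")

#' @rdname detect_peaks
#' @export
detect_peaks.trajectory <- function(x, coord = "z", refine = TRUE, ...) {
  s <- if (is.character(coord)) x$states[, coord] else x$states[, coord]
  name <- if (is.character(coord)) coord else colnames(x$states)[coord]
  detect_peaks_series(s, trajectory_times(x), refine = refine, coord = name)
}

#' @rdname detect_peaks
#' @param t sample times (default a unit grid).
#' @export
detect_peaks.numeric <- function(x, t = seq_along(x) - 1, refine = FALSE,
                                 coord = "series", ...) {
  detect_peaks_series(x, t, refine = refine, coord = coord)
}

detect_peaks_series <- function(s, t, refine, coord) {
  n <- length(s)
  if (n < 3L) pk_stop("need at least 3 samples to detect peaks", "peaknet_insufficient_data")
  h <- t[2] - t[1]
  left <- s[1:(n - 2)]; mid <- s[2:(n - 1)]; right <- s[3:n]
  cand <- which(left < mid & mid >= right) + 1L
  if (length(cand) == 0L) {
    return(peak_sequence(numeric(0), numeric(0), coord = coord))
  }
  # plateau of > 2 equal consecutive samples around the candidate
  run <- rle(s)
  plateau_idx <- with(run, {
    ends <- cumsum(lengths)
    starts <- ends - lengths + 1L
    long <- which(lengths > 2L)
    unlist(mapply(seq, starts[long], ends[long], SIMPLIFY = FALSE), use.names = FALSE)
  })
  degen <- cand %in% plateau_idx
  times <- t[cand]
  heights <- s[cand]
  if (refine) {
    a <- (s[cand - 1L] - 2 * s[cand] + s[cand + 1L]) / 2
    b <- (s[cand + 1L] - s[cand - 1L]) / 2
    ok <- a < 0 & !degen
    du <- ifelse(ok, -b / (2 * a), 0)
    times <- t[cand] + du * h
    heights <- s[cand] + ifelse(ok, -b^2 / (4 * a), 0)
  }
  peak_sequence(times, heights, coord = coord, degenerate = degen)
}

#' Consecutive peak pairs defining the empirical successor map
#'
#' Builds the ordered pairs `(z_n, z_{n+1})` whose graph is the empirical
#' one-dimensional peak map `P : z_n -> z_{n+1}`.
#'
#' @param peaks a [peak_sequence()] or a numeric height vector (>= 2 peaks).
#' @return a data.frame of class `peak_pairs` with columns `z`, `z_next`.
#' @export
build_peak_pairs <- function(peaks) {
  z <- if (inherits(peaks, "peak_sequence")) peaks$heights else as.numeric(peaks)
  if (length(z) < 2L) pk_stop("need at least 2 peaks", "peaknet_insufficient_data")
  out <- data.frame(z = z[-length(z)], z_next = z[-1L])
  class(out) <- c("peak_pairs", "data.frame")
  out
}

#' Local slope of the empirical peak map
#'
#' Least-squares slope of `z_{n+1}` against `z_n` restricted to pairs with
#' `|z_n - z0| < window_eps`; this estimates the map derivative `P'(z0)`
#' from orbit data alone.
#'
#' @param pairs a [build_peak_pairs()] result.
#' @param z0 evaluation point.
#' @param window_eps window half-width.
#' @return the estimated slope (a single number).
#' @export
local_slope <- function(pairs, z0, window_eps) {
  keep <- abs(pairs$z - z0) < window_eps
  if (sum(keep) < 2L) {
    pk_stop("fewer than 2 pairs inside the window", "peaknet_insufficient_data")
  }
  x <- pairs$z[keep]; y <- pairs$z_next[keep]
  vx <- stats::var(x)
  if (!is.finite(vx) || vx < .Machine$double.eps * max(1, mean(x)^2)) {
    pk_stop("in-window predecessors are numerically identical; slope is undetermined",
            "peaknet_insufficient_data")
  }
  unname(stats::cov(x, y) / vx)
}
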