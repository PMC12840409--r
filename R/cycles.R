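#' Cycle multiplier of a periodic orbit of a 1D map
#'
#' The product of the map derivative around the cycle,
#' \deqn{\Lambda_T = \prod_{j=0}^{T-1} P'(z_j),}
#' which is invariant under cyclic rotation of the points and governs local
#' asymptotic stability (`|Lambda_T| < 1` iff the cycle attracts).
#'
#' @param points the cycle points `z_0 .. z_{T-1}`.
#' @param deriv derivative evaluator `P'`.
#' @return the multiplier (a single number).
#' @export
cycle_multiplier <- function(points, deriv) {
  d <- vapply(points, deriv, numeric(1))
  if (any(!is.finite(d))) {
    pk_stop("non-finite derivative at a cycle point", "peaknet_nonfinite")
  }
  prod(d)
}

#' Classify stability from a multiplier or spectral radius
#'
#' `|Lambda| < 1` is stable, `|Lambda| > 1` unstable; within `tol` of 1 the
#' linear criterion is inconclusive (saddle-node or period-doubling
#' boundary) and the label is `"marginal"`.
#'
#' @param Lambda multiplier (or spectral radius) value.
#' @param tol marginality tolerance on `||Lambda| - 1|`.
#' @return `"stable"`, `"unstable"`, or `"marginal"`.
#' @export
classify_stability <- function(Lambda, tol = 1e-6) {
  check_finite(Lambda, "Lambda")
  a <- abs(Lambda)
  if (abs(a - 1) < tol) "marginal" else if (a < 1) "stable" else "unstable"
}

compose_map <- function(P, T) {
  function(z) {
    for (j in seq_len(T)) z <- P(z)
    z
  }
}

#' Locate periodic orbits of a 1D map
#'
#' Finds all roots of `P^T(z) - z` for `T = 1..T_max` on a bracketing grid
#' over `interval`, refines each bracket by bisection to `tol`, groups roots
#' into orbits, and keeps only cycles of minimal period (a T-cycle is
#' dropped when some divisor of T reproduces the same point set). Each cycle
#' carries its multiplier from the derivative chain (analytic derivative if
#' the map provides one, central differences otherwise) and the resulting
#' stability label.
#'
#' @param P a continuous 1D map (e.g. [logistic_map()] or an interpolated
#'   empirical peak map).
#' @param interval numeric length-2 search interval.
#' @param T_max largest period searched.
#' @param tol bisection tolerance on the root.
#' @param deriv optional derivative `P'`; defaults to the map's own, then
#'   to numeric differentiation.
#' @param grid_n bracketing grid resolution.
#' @return a list of `cycle_record` lists with fields `points`, `period`,
#'   `multiplier`, `residual`, `stability`, plus attribute `degenerate`
#'   (TRUE when the map is identity-like on the grid).
#' @examples
#' cyc <- find_cycles(logistic_map(3.2), c(0, 1), T_max = 2)
#' vapply(cyc, `[[`, integer(1), "period")
#' @export
find_cycles <- function(P, interval, T_max, tol = 1e-10, deriv = NULL,
                        grid_n = 512L) {
  if (T_max < 1) pk_stop("T_max must be >= 1", "peaknet_invalid")
  deriv <- map_deriv(P, deriv)
  grid <- seq(interval[1], interval[2], length.out = grid_n)
  records <- list()
  degenerate <- FALSE
  for (T in seq_len(T_max)) {
    PT <- compose_map(P, T)
    g <- vapply(grid, function(z) PT(z) - z, numeric(1))
    near0 <- mean(abs(g) < 10 * tol)
    if (near0 > 0.5) {
      degenerate <- TRUE
      next  # identity-like iterate: every grid point "is" a root
    }
    sgn <- sign(g)
    idx <- which(sgn[-length(sgn)] * sgn[-1] < 0 | g[-length(g)] == 0)
    for (i in idx) {
      root <- bisect_root(function(z) PT(z) - z, grid[i], grid[i + 1L], tol)
      if (is.null(root)) next
      orbit <- iterate_map(P, root, T)
      # minimal period: the smallest divisor of T that already closes
      min_T <- T
      for (Tp in seq_len(T - 1L)) {
        if (T %% Tp != 0L) next
        shifted <- orbit[((seq_len(T) - 1L) %% Tp) + 1L]
        if (all(abs(orbit - shifted) < 100 * tol)) { min_T <- Tp; break }
      }
      if (min_T < T) next  # already reported at its minimal period
      # dedupe: same orbit found from another phase
      dup <- any(vapply(records, function(rec) {
        rec$period == T && min(abs(rec$points[1] - orbit)) < 100 * tol
      }, logical(1)))
      if (dup) next
      mult <- tryCatch(cycle_multiplier(orbit, deriv), error = function(e) NA_real_)
      records[[length(records) + 1L]] <- structure(
        list(points = orbit, period = as.integer(T), multiplier = mult,
             residual = abs(PT(orbit[1L]) - orbit[1L]),
             stability = if (is.na(mult)) NA_character_ else classify_stability(mult),
             multiplier_flagged = is.na(mult)),
        class = "cycle_record")
    }
  }
  structure(records, degenerate = degenerate)
}

bisect_root <- function(g, a, b, tol, max_iter = 200L) {
  fa <- g(a); fb <- g(b)
  if (!is.finite(fa) || !is.finite(fb)) return(NULL)
  if (fa == 0) return(a)
  if (fb == 0) return(b)
  if (fa * fb > 0) return(NULL)
  for (i in seq_len(max_iter)) {
    m <- (a + b) / 2
    fm <- g(m)
    if (!is.finite(fm)) return(NULL)
    if (abs(b - a) < tol || fm == 0) return(m)
    if (fa * fm < 0) { b <- m; fb <- fm } else { a <- m; fa <- fm }
  }
  (a + b) / 2
}
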