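#' Recurrence profile of a peak-height sequence
#'
#' For each candidate period `T = 1..T_max` the returns
#' `d_n(T) = |z_{n+T} - z_n|` are counted against the tolerance `epsilon`:
#' \deqn{r_T = \frac{1}{N - T}\,\#\{n : d_n(T) < \epsilon\}.}
#' `r_T = 1` signals exact period-T recurrence of the observed heights.
#'
#' @param heights numeric peak heights (or a [peak_sequence()]).
#' @param T_max largest period tested; must be `< length(heights)`.
#' @param epsilon recurrence tolerance; default `1e-3` of the height range.
#' @return a list of class `recurrence_profile` with `r` (named by T),
#'   `epsilon`, `T_max`.
#' @export
recurrence_profile <- function(heights, T_max, epsilon = NULL) {
  z <- if (inherits(heights, "peak_sequence")) heights$heights else as.numeric(heights)
  N <- length(z)
  if (N <= T_max) pk_stop("need more peaks than T_max", "peaknet_insufficient_data")
  if (is.null(epsilon)) {
    rng <- diff(range(z))
    epsilon <- if (rng > 0) 1e-3 * rng else 1e-12
  }
  check_positive(epsilon, "epsilon")
  r <- vapply(seq_len(T_max), function(T) {
    mean(abs(z[(1 + T):N] - z[1:(N - T)]) < epsilon)
  }, numeric(1))
  names(r) <- seq_len(T_max)
  structure(list(r = r, epsilon = epsilon, T_max = as.integer(T_max)),
            class = "recurrence_profile")
}

#' Classify the dynamical regime of a peak sequence
#'
#' Recurrence-based decision rule: compute the recurrence profile; periods
#' with `r_T >= theta` are periodicity candidates, examined in increasing
#' order. For each candidate the cycle multiplier is estimated empirically:
#' the candidate cycle nodes are the most recent `T` heights, and `P'` at
#' each node is the windowed least-squares slope of the successor pairs
#' (chained into `Lambda_T`). If no candidate exists the regime shows no
#' observable periodicity and, absent an attracting cycle, is labelled
#' `non_periodic_unstable`. A candidate with `|Lambda_T| < 1` yields
#' `periodic_stable` when the recurrence is essentially exact
#' (`r_T >= strict`), and `non_periodic_stable` otherwise; `|Lambda_T|`
#' within `marginal_tol` of 1 yields `marginal`. When the orbit has already
#' collapsed onto the cycle to machine precision the windowed fit is
#' degenerate; such a perfectly recurrent candidate is treated as attracting
#' with the multiplier recorded as `NA`.
#'
#' @param peaks a [peak_sequence()] or numeric heights.
#' @param T_max largest period tested.
#' @param epsilon recurrence tolerance (default `1e-3` of the height range).
#' @param theta majority threshold on `r_T` (default 0.8).
#' @param window_eps slope-fit window (default 5% of the height range).
#' @param marginal_tol tolerance for the marginal label.
#' @param strict recurrence fraction treated as exact periodicity.
#' @return a list of class `regime_label` with `label`, `evidence`
#'   (candidate `T`, `Lambda`, `r_T`), and the full `profile`.
#' @export
classify_regime <- function(peaks, T_max = 12L, epsilon = NULL, theta = 0.8,
                            window_eps = NULL, marginal_tol = 1e-6,
                            strict = 0.99) {
  z <- if (inherits(peaks, "peak_sequence")) peaks$heights else as.numeric(peaks)
  prof <- recurrence_profile(z, T_max, epsilon)
  rng <- diff(range(z))
  if (is.null(window_eps)) window_eps <- if (rng > 0) 0.05 * rng else 1e-6
  pairs <- build_peak_pairs(z)
  cand <- as.integer(names(prof$r)[prof$r >= theta])
  evidence <- list(T = NA_integer_, Lambda = NA_real_, r_T = NA_real_)
  label <- "non_periodic_unstable"
  for (T in sort(cand)) {
    nodes <- utils::tail(z, T)
    slopes <- numeric(T)
    degenerate <- FALSE
    for (j in seq_len(T)) {
      slopes[j] <- tryCatch(local_slope(pairs, nodes[j], window_eps),
                            error = function(e) { NA_real_ })
      if (is.na(slopes[j])) degenerate <- TRUE
    }
    Lambda <- if (degenerate) NA_real_ else prod(slopes)
    attracting <- degenerate || (is.finite(Lambda) && abs(Lambda) < 1)
    if (!degenerate && abs(abs(Lambda) - 1) < marginal_tol) {
      label <- "marginal"
      evidence <- list(T = T, Lambda = Lambda, r_T = unname(prof$r[T]))
      break
    }
    if (attracting) {
      label <- if (prof$r[T] >= strict) "periodic_stable" else "non_periodic_stable"
      evidence <- list(T = T, Lambda = Lambda, r_T = unname(prof$r[T]))
      break
    }
    # candidate examined but repelling: keep looking, remember the evidence
    evidence <- list(T = T, Lambda = Lambda, r_T = unname(prof$r[T]))
  }
  structure(list(label = label, evidence = evidence, profile = prof),
            class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  cat(sprintf("Regime: %s", x$label))
  if (!is.na(x$evidence$T)) {
    cat(sprintf("  (T = %d, Lambda = %s, r_T = %.3f)", x$evidence$T,
                format(x$evidence$Lambda, digits = 4), x$evidence$r_T))
  }
  cat("\n")
  invisible(x)
}
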