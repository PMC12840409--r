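#' Regime report for a network run
#'
#' Classifies an activity history as zeroed, periodic, or non-periodic, and
#' evaluates the three stationarity criteria of the periodic regime on the
#' mean-activity series:
#' * zeroing: first index `k > k0` where every neuron is inactive
#'   (`T_life`), the network's death time;
#' * exact periodicity: the smallest `T <= T_max` with
#'   `N_i(k + T) = N_i(k)` for every neuron over the interval;
#' * amplitude: relative change of the windowed amplitude
#'   `A_k = max - min` of the mean activity over one candidate period,
#'   `|A_{k+T} - A_k| / A_k < eps`;
#' * inter-peak period: successive peak spacings `T_k` of the mean
#'   activity satisfy `|T_{k+1} - T_k| / T_k < delta_T`;
#' * autocorrelation: the biased autocorrelation of the mean-removed mean
#'   activity satisfies `R(T) >= R_min` and `|R(2T) - R(T)| < R_tol`.
#'
#' The label is `"zeroed"`, `"periodic"` (exact periodicity found), or
#' `"non_periodic_stable"` (activity persists without an exact period).
#'
#' @param activity binary matrix, time in rows, neurons in columns (e.g.
#'   `kp_run(..., record_activity = TRUE)$activity`).
#' @param k0 steps (e.g. the stimulation window) excluded from zeroing
#'   detection.
#' @param interval integer range of rows analysed (default: all after
#'   `k0`).
#' @param T_max largest exact period tested.
#' @param eps amplitude criterion tolerance.
#' @param delta_T period criterion tolerance.
#' @param R_min autocorrelation floor.
#' @param R_tol tolerance on `R(k+T) ~ R(k)`.
#' @return a list of class `kp_regime_report`.
#' @export
kp_regime_report <- function(activity, k0 = 0L, interval = NULL,
                             T_max = 64L, eps = 0.05, delta_T = 0.05,
                             R_min = 0.1, R_tol = 0.05) {
  m <- nrow(activity)
  if (is.null(interval)) interval <- c(k0 + 1L, m)
  if (interval[1] < 1L || interval[2] > m || interval[1] >= interval[2]) {
    pk_stop("interval outside history", "peaknet_invalid")
  }
  win <- activity[interval[1]:interval[2], , drop = FALSE]
  mean_act <- rowMeans(win)

  # zeroing: the all-inactive state is absorbing without stimulation, so the
  # network is zeroed when a suffix of the window is entirely inactive
  row_active <- rowSums(win) > 0L
  zeroed <- FALSE; T_life <- NA_integer_
  if (!row_active[length(row_active)] && any(row_active)) {
    first_dead <- max(which(row_active)) + 1L
    if (first_dead + interval[1] - 1L > k0) {
      zeroed <- TRUE
      T_life <- first_dead + interval[1] - 1L
    }
  } else if (!any(row_active)) {
    zeroed <- TRUE
    T_life <- interval[1]
  }

  # exact periodicity of the full binary matrix
  rows <- nrow(win)
  period <- NA_integer_
  for (T in seq_len(min(T_max, rows - 1L))) {
    if (all(win[(T + 1):rows, ] == win[1:(rows - T), ])) { period <- T; break }
  }
  periodic <- !is.na(period) && !zeroed

  amplitude_ok <- NA; period_ok <- NA; autocorr_ok <- NA
  A_vals <- NULL; peak_spacings <- NULL; R_T <- NA_real_
  Tc <- if (periodic) period else NA_integer_
  if (!zeroed) {
    pk <- detect_peaks(mean_act)
    if (length(pk$times) >= 3L) {
      peak_spacings <- diff(pk$times)
      period_ok <- all(abs(diff(peak_spacings)) / peak_spacings[-length(peak_spacings)] < delta_T)
      if (is.na(Tc)) Tc <- as.integer(round(stats::median(peak_spacings)))
    }
    if (!is.na(Tc) && Tc >= 1L && rows >= 3L * Tc) {
      n_win <- floor(rows / Tc)
      A_vals <- vapply(seq_len(n_win), function(w) {
        seg <- mean_act[((w - 1L) * Tc + 1L):(w * Tc)]
        max(seg) - min(seg)
      }, numeric(1))
      nz <- A_vals[-length(A_vals)] != 0
      amplitude_ok <- all(abs(diff(A_vals))[nz] / A_vals[-length(A_vals)][nz] < eps) &&
        !any(A_vals == 0 & c(A_vals[-1], A_vals[length(A_vals)]) != 0)
      ac <- stats::acf(mean_act - mean(mean_act), lag.max = min(2L * Tc, rows - 1L),
                       plot = FALSE, demean = FALSE)$acf[, 1, 1]
      R_T <- ac[Tc + 1L]
      R_2T <- if (length(ac) > 2L * Tc) ac[2L * Tc + 1L] else NA_real_
      autocorr_ok <- isTRUE(R_T >= R_min) &&
        (is.na(R_2T) || abs(R_2T - R_T) < R_tol)
    }
  }
  label <- if (zeroed) "zeroed" else if (periodic) "periodic" else "non_periodic_stable"
  structure(list(zeroed = zeroed, T_life = T_life,
                 periodic = periodic, period = period,
                 amplitude_ok = amplitude_ok, period_ok = period_ok,
                 autocorr_ok = autocorr_ok,
                 measured = list(A = A_vals, peak_spacings = peak_spacings,
                                 R_T = R_T),
                 label = label),
            class = "kp_regime_report")
}

#' @export
print.kp_regime_report <- function(x, ...) {
  cat(sprintf("KP regime: %s", x$label))
  if (x$periodic) cat(sprintf(" (T = %d)", x$period))
  if (x$zeroed) cat(sprintf(" (T_life = %d)", x$T_life))
  cat("\n")
  invisible(x)
}

#' Block-frequency profile of neural oscillations
#'
#' Each neuron's binary activity over the interval is split into maximal
#' constant blocks (all-zero or all-one); a block of length `t_j`
#' corresponds to the oscillation frequency `1 / (2 t_j)`. The profile
#' \deqn{g(t_j) = \frac{\sum_{m=1}^{n} \sum_i c_{ij}^{(m)} t_j^{(m)}}{n\,l}}
#' weights each block length by the total time spent in blocks of that
#' length, so `sum_j g(t_j) = 1` exactly. Interval boundaries are snapped
#' to activity transitions of each neuron before decomposition.
#'
#' @param activity binary matrix (time x neurons).
#' @param interval integer row range analysed (default all rows).
#' @return a list of class `frequency_profile` with `lengths` (`t_j`), `g`,
#'   `frequency` (`1/(2 t_j)`), per-neuron block `counts`, and the
#'   observation length `l`.
#' @export
frequency_profile <- function(activity, interval = NULL) {
  m <- nrow(activity)
  if (is.null(interval)) interval <- c(1L, m)
  if (interval[1] >= interval[2]) pk_stop("empty interval", "peaknet_invalid")
  n <- ncol(activity)
  tally <- new.env()
  total <- 0
  counts <- vector("list", n)
  for (i in seq_len(n)) {
    s <- activity[interval[1]:interval[2], i]
    # snap to transitions: drop the (possibly clipped) first and last block
    r <- rle(as.integer(s))
    lens <- r$lengths
    if (length(lens) > 2L) lens <- lens[-c(1L, length(lens))]
    counts[[i]] <- table(lens)
    for (L in lens) {
      key <- as.character(L)
      tally[[key]] <- (if (is.null(tally[[key]])) 0 else tally[[key]]) + L
      total <- total + L
    }
  }
  if (total == 0) pk_stop("no complete blocks in the interval", "peaknet_insufficient_data")
  lengths <- sort(as.integer(ls(tally)))
  g <- vapply(as.character(lengths), function(k) tally[[k]], numeric(1)) / total
  structure(list(lengths = lengths, g = unname(g),
                 frequency = 1 / (2 * lengths), counts = counts,
                 l = total / n),
            class = "frequency_profile")
}
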