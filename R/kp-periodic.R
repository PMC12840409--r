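#' Stationary periodic solution of a leaky recurrence
#'
#' For the scalar recurrence `A(k+1) = a A(k) + b(k)` with `a` in `[0, 1)`
#' and `b` periodic with period `T`, the long-run limit is itself
#' T-periodic with closed form
#' \deqn{A(k) = \frac{1}{1 - a^T} \sum_{i=0}^{T-1} a^{T-1-i}\, b(k+i).}
#' This is the template for every slow variable of the network (efficacies,
#' base weights) once the activities are periodic.
#'
#' @param a decay constant in `[0, 1)`.
#' @param b numeric vector of one period of the forcing, `b[k+1] = b(k)`.
#' @return numeric vector `A(k)` for `k = 0..T-1`.
#' @examples
#' periodic_closed_form(0.5, c(1, 0))  # alternating forcing
#' @export
periodic_closed_form <- function(a, b) {
  if (abs(a) >= 1) pk_stop("divergent: need |a| < 1 (a = 1 has no stationary limit)",
                           "peaknet_degenerate")
  T <- length(b)
  vapply(seq_len(T) - 1L, function(k) {
    i <- seq_len(T) - 1L
    sum(a^(T - 1 - i) * b[((k + i) %% T) + 1L]) / (1 - a^T)
  }, numeric(1))
}

#' Stationary base weight of one link in a periodic regime
#'
#' With activities `N_i`, `N_j` periodic of period `T`, the delayed-Hebb
#' base weight settles on
#' \deqn{W^0_{ij}(k) = \frac{\upsilon}{1-(1-\mu)^T}
#'   \sum_{i=0}^{T-1} (1-\mu)^{T-1-i} N_i(k+i) N_j(k+i-1),}
#' i.e. [periodic_closed_form()] with `a = 1 - mu` and forcing
#' `b(k) = upsilon N_i(k) N_j(k-1)`. Two permanently co-active neurons give
#' the constant `upsilon / mu`; a never-coincident pair gives 0.
#'
#' @param Ni,Nj one period of each binary activity sequence (length `T`).
#' @param mu weight dissipation (> 0).
#' @param upsilon Hebb gain.
#' @return numeric vector `W0_ij(k)` over one period.
#' @export
link_weights_periodic <- function(Ni, Nj, mu, upsilon) {
  if (mu == 0) pk_stop("mu = 0: base weight is non-stationary", "peaknet_degenerate")
  if (length(Ni) != length(Nj)) pk_stop("Ni and Nj must share a period", "peaknet_invalid")
  T <- length(Ni)
  b <- upsilon * Ni * Nj[((seq_len(T) - 2L) %% T) + 1L]  # N_j(k-1), wrapped
  periodic_closed_form(1 - mu, b)
}

#' Count distinct link types in a periodic activity history
#'
#' In a period-T regime each ordered neuron pair `(i, j)` contributes the
#' product sequence `N_i(k) N_j(k-1)` over one period; pairs whose product
#' sequences coincide up to a cyclic phase shift share the same stationary
#' weight profile and constitute one link type. This returns the empirical
#' number of distinct types.
#'
#' @param history binary activity matrix (time in rows, neurons in
#'   columns), covering at least `2 T` post-transient steps.
#' @param T the period.
#' @return integer count of distinct product-sequence types.
#' @export
count_link_types <- function(history, T) {
  if (nrow(history) < 2 * T) {
    pk_stop("history must cover at least 2 T steps", "peaknet_insufficient_data")
  }
  # verify periodicity over the window
  m <- nrow(history)
  if (!all(history[(T + 1):m, ] == history[1:(m - T), ])) {
    pk_stop("history is not T-periodic", "peaknet_degenerate")
  }
  n <- ncol(history)
  canon <- function(v) {
    T <- length(v)
    rots <- vapply(seq_len(T) - 1L, function(s) {
      paste(v[((seq_len(T) - 1L + s) %% T) + 1L], collapse = "")
    }, character(1))
    min(rots)
  }
  types <- character(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      k <- (T + 1):(2 * T)  # one full period with a valid k-1 predecessor
      prod_seq <- history[k, i] * history[k - 1L, j]
      types <- c(types, canon(prod_seq))
    }
  }
  length(unique(types))
}
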