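#' Block embedding of a 1D map into m dimensions
#'
#' The product system `F(x) = (P(x_1), lambda_2 x_2, ..., lambda_m x_m)`
#' whose first axis is an invariant 1D manifold conjugate to `P` by the
#' identity chart; the remaining axes carry prescribed linear transverse
#' rates. Used to exercise the multiplier / monodromy correspondence with
#' full control of the transverse spectrum.
#'
#' @param P 1D map.
#' @param transverse_rates numeric vector of transverse rates
#'   `lambda_2 .. lambda_m`.
#' @param deriv optional `P'`.
#' @return a list with `map` and `jacobian` functions on `R^m`,
#'   `m = length(transverse_rates) + 1`.
#' @export
embed_block_map <- function(P, transverse_rates, deriv = NULL) {
  deriv <- map_deriv(P, deriv)
  m <- length(transverse_rates) + 1L
  list(
    map = function(x) c(P(x[1]), transverse_rates * x[-1]),
    jacobian = function(x) {
      J <- diag(c(0, transverse_rates), nrow = m)
      J[1, 1] <- deriv(x[1])
      J
    },
    m = m)
}

#' Stability-correspondence harness for an embedded 1D map
#'
#' Constructs the block embedding of `P` around a fixed point `u_star`,
#' computes the full Jacobian at `(u*, 0, ..., 0)`, its spectral radius,
#' and checks the biconditional
#' `|P'(u*)| < 1  <=>  rho(DF) < 1`. With contracting transverse rates the
#' two verdicts always agree (`rho = max(|P'|, |lambda_trans|)` stays below
#' 1 exactly when `|P'| < 1`). When some `|lambda_trans| >
#' max(1, |P'(u*)|)` the spectral radius is set by the transverse part and
#' the biconditional fails; the report flags this assumption violation
#' rather than asserting either reading of the correspondence.
#'
#' @param P 1D map.
#' @param u_star fixed point of `P` (checked; the harness uses it as
#'   given).
#' @param transverse_rates transverse rates, each with `|rate| != 1`.
#' @param deriv optional `P'`; numeric differentiation (flagged) otherwise.
#' @return a list of class `embedding_report` with `tangential`
#'   (`P'(u*)`), `transverse`, `rho`, `stable_P`, `stable_F`,
#'   `equivalent`, `assumption_violated`, `deriv_numeric`.
#' @export
conjugate_embedding_test <- function(P, u_star, transverse_rates,
                                     deriv = NULL) {
  if (any(abs(abs(transverse_rates) - 1) < 1e-12)) {
    pk_stop("transverse rates must have |rate| != 1", "peaknet_invalid")
  }
  deriv_numeric <- is.null(deriv) && is.null(attr(P, "deriv"))
  dP <- map_deriv(P, deriv)(u_star)
  if (!is.finite(dP)) pk_stop("P' unavailable at u*", "peaknet_nonfinite")
  emb <- embed_block_map(P, transverse_rates, deriv)
  x_star <- c(u_star, numeric(length(transverse_rates)))
  J <- emb$jacobian(x_star)
  rho <- spectral_radius(J)
  stable_P <- abs(dP) < 1
  stable_F <- rho < 1
  structure(list(tangential = dP, transverse = transverse_rates, rho = rho,
                 stable_P = stable_P, stable_F = stable_F,
                 equivalent = stable_P == stable_F,
                 assumption_violated = max(abs(transverse_rates)) > max(1, abs(dP)) &&
                   stable_P != stable_F,
                 deriv_numeric = deriv_numeric),
            class = "embedding_report")
}

#' @export
print.embedding_report <- function(x, ...) {
  cat(sprintf("Embedding: |P'(u*)| = %.4g, rho(DF) = %.4g -> %s\n",
              abs(x$tangential), x$rho,
              if (x$equivalent) "verdicts agree"
              else "verdicts disagree (transverse-dominated)"))
  invisible(x)
}
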