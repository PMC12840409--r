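# internal helpers shared across modules

pk_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "peaknet_error"), call = call))
}

check_finite <- function(x, what = "input") {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    pk_stop(sprintf("%s must be finite numeric", what), "peaknet_nonfinite")
  }
  invisible(x)
}

check_positive <- function(x, what = "value") {
  check_finite(x, what)
  if (any(x <= 0)) pk_stop(sprintf("%s must be > 0", what), "peaknet_invalid")
  invisible(x)
}

# max-norm used for all stopping and step-doubling error rules
max_norm <- function(x) max(abs(x))

#' Spectral radius of a square matrix
#'
#' Largest modulus among the eigenvalues, computed with the dense
#' nonsymmetric eigensolver.
#'
#' @param M a square numeric matrix.
#' @return a single non-negative number.
#' @export
spectral_radius <- function(M) {
  max(Mod(eigen(M, only.values = TRUE)$values))
}

# distinct values up to an absolute tolerance (sorted input not required)
count_distinct <- function(x, tol) {
  x <- sort(x[is.finite(x)])
  if (length(x) == 0L) return(0L)
  if (length(x) == 1L) return(1L)
  sum(diff(x) > tol) + 1L
}

# symmetric Hausdorff distance between two finite point sets in R^1
hausdorff_dist <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(Inf)
  d_ab <- max(vapply(a, function(p) min(abs(b - p)), numeric(1)))
  d_ba <- max(vapply(b, function(p) min(abs(a - p)), numeric(1)))
  max(d_ab, d_ba)
}
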