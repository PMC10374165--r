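## Optimal polynomial preprocessing J(Y) of the data matrix.
##
## The AdaTAP reduction of the quartic-noise posterior yields an effective
## pairwise model whose coupling matrix is a polynomial in Y:
##     J(Y) = mu sqrt(lambda) Y - gamma lambda Y^2 + gamma sqrt(lambda) Y^3,
## and for the pure sextic potential (reconstructed coefficient table)
##     J6(Y) = xi sqrt(lambda) Y^5 - xi lambda Y^4 - xi lambda Y^2.
## In the Wigner case (mu = 1, gamma = 0) this is just sqrt(lambda) Y.
## J maps the noise bulk to the negative axis while pushing the signal
## outlier further out on the positive side ("spectral cleaning").

#' Preprocessing polynomial for an ensemble
#'
#' Returns the coefficients \eqn{(c_1, \dots, c_K)} of
#' \eqn{J(Y) = \sum_k c_k Y^k}, the optimal data preprocessing for a
#' degree-\eqn{K+1} polynomial potential.  \code{snr = 0} gives the zero
#' polynomial.  Trailing zero coefficients (the Wigner limit of the quartic
#' family) are kept so \code{degree} always equals potential degree - 1;
#' algorithms trim them internally.
#'
#' @param spec An [ensemble_spec()].
#' @param snr \eqn{\lambda \ge 0}.
#' @return Object of class \code{"preprocess_poly"}: fields
#'   \code{coefficients}, \code{degree}, \code{snr}, \code{source}.
#' @examples
#' j_coefficients(ensemble_spec("goe"), 4)$coefficients        # (2, 0, 0) -> 2 Y
#' j_coefficients(ensemble_spec("quartic", 0), 5)$coefficients
#' @export
j_coefficients <- function(spec, snr) {
  stopifnot(inherits(spec, "ensemble_spec"), snr >= 0)
  sl <- sqrt(snr)
  out <- switch(spec$family,
    goe = list(coefficients = c(sl, 0, 0), source = "quartic_adatap"),
    quartic = list(
      coefficients = c(spec$mu * sl, -spec$gamma * snr, spec$gamma * sl),
      source = "quartic_adatap"),
    sextic = list(
      ## reconstructed from the rendered J6; x^3 term absent in the source
      coefficients = c(0, -spec$xi * snr, 0, -spec$xi * snr, spec$xi * sl),
      source = "sextic_adatap"))
  structure(list(coefficients = out$coefficients,
                 degree = length(out$coefficients),
                 snr = snr, source = out$source),
            class = "preprocess_poly")
}

#' Custom preprocessing polynomial
#'
#' Wraps user-supplied coefficients \eqn{(c_1, \dots, c_K)} (e.g. learned
#' from data) in the same container used by [j_coefficients()].
#'
#' @param coefficients Numeric vector, \code{coefficients[k]} multiplying
#'   \eqn{Y^k}.
#' @param snr The \eqn{\lambda} the coefficients were built for.
#' @return A \code{"preprocess_poly"} with \code{source = "custom"}.
#' @export
custom_preprocess <- function(coefficients, snr = NA_real_) {
  stopifnot(is.numeric(coefficients), length(coefficients) >= 1)
  structure(list(coefficients = coefficients, degree = length(coefficients),
                 snr = snr, source = "custom"),
            class = "preprocess_poly")
}

## scalar version J(x), vectorized
j_scalar <- function(poly, x) {
  out <- 0
  for (k in rev(seq_along(poly$coefficients))) out <- (out + poly$coefficients[k]) * x
  out
}

#' Apply a preprocessing polynomial to a symmetric matrix
#'
#' Materializes \eqn{J(Y)} by Horner iteration on matrix products.  The
#' result shares the eigenbasis of the input and has eigenvalues
#' \eqn{J(\lambda_i)}.  Intended for moderate \eqn{n} diagnostics (spectral
#' cleaning plots); inside AMP iterations use [apply_poly_matvec()], which
#' only ever forms matrix-vector products.
#'
#' @param data Symmetric matrix.
#' @param poly A \code{"preprocess_poly"}.
#' @return Symmetric matrix \eqn{J(data)}.
#' @export
apply_preprocessing <- function(data, poly) {
  if (!is.matrix(data) || nrow(data) != ncol(data))
    stop("data must be a square matrix")
  if (max(abs(data - t(data))) > 1e-8 * max(1, max(abs(data))))
    stop("data must be symmetric")
  cf <- poly$coefficients
  n <- nrow(data)
  out <- diag(cf[length(cf)], n)
  for (k in rev(seq_len(length(cf) - 1))) {
    out <- out %*% data
    out <- out + diag(cf[k], n)
  }
  out <- out %*% data
  (out + t(out)) / 2
}

#' Matrix-polynomial times vector without forming powers
#'
#' Computes \eqn{J(Y)v = \sum_k c_k Y^k v} using \eqn{K} matrix-vector
#' products; optionally returns the intermediate vectors \eqn{Y^k v}
#' (needed by the multistage algorithms).
#'
#' @param data Symmetric matrix \eqn{Y}.
#' @param poly A \code{"preprocess_poly"}.
#' @param v Vector.
#' @param keep_powers If \code{TRUE}, also return the list of \eqn{Y^k v}.
#' @return The vector \eqn{J(Y)v}, or a list \code{(jv, powers)}.
#' @export
apply_poly_matvec <- function(data, poly, v, keep_powers = FALSE) {
  cf <- poly$coefficients
  acc <- numeric(length(v))
  cur <- v
  pw <- if (keep_powers) vector("list", length(cf)) else NULL
  for (k in seq_along(cf)) {
    cur <- as.numeric(data %*% cur)
    if (keep_powers) pw[[k]] <- cur
    if (cf[k] != 0) acc <- acc + cf[k] * cur
  }
  if (keep_powers) list(jv = acc, powers = pw) else acc
}
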