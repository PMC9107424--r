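#' Log-Euclidean geometry on the SPD cone
#'
#' @description
#' The symmetric positive definite (SPD) matrices of a fixed size form a
#' cone-shaped manifold.  Under the Log-Euclidean metric the matrix
#' logarithm maps this manifold isometrically onto the flat space of
#' symmetric matrices, so geodesic distances, tangent matrices and
#' parallel transport all reduce to ordinary linear algebra in
#' log-coordinates.  These are the primitives on which the sample
#' selection method is built: a functional connectome (a correlation
#' matrix, possibly singular) is first nudged onto the SPD cone by adding
#' a small multiple of the identity, and pairwise differences between
#' connectomes are then represented as tangent matrices at the identity.
#'
#' All matrix functions are computed by symmetric eigendecomposition and
#' the reconstruction is explicitly re-symmetrized, so outputs are exactly
#' symmetric.
#'
#' @name spd_geometry
NULL

.symmetrize <- function(M) (M + t(M)) / 2

.check_square_symmetric <- function(M, what = "matrix", tol = .tol("symmetry")) {
  if (!is.matrix(M) || !is.numeric(M)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  if (nrow(M) != ncol(M)) {
    stop(what, " must be square, got ", nrow(M), "x", ncol(M), call. = FALSE)
  }
  if (anyNA(M) || any(!is.finite(M))) {
    stop(what, " contains NA or non-finite entries", call. = FALSE)
  }
  asym <- max(abs(M - t(M)))
  if (asym > tol) {
    stop(what, " is not symmetric (max asymmetry ", format(asym), ")",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate a correlation matrix
#'
#' Checks the invariants expected of a functional connectome: square,
#' symmetric, unit diagonal, entries in \eqn{[-1, 1]}, and positive
#' semidefinite up to numerical noise.
#'
#' @param C Numeric square matrix of Pearson correlations.
#' @param subject Optional subject id used in error messages.
#' @return Invisibly `TRUE`; stops with a diagnostic otherwise.
#' @export
check_correlation <- function(C, subject = NULL) {
  who <- if (is.null(subject)) "correlation matrix" else
    paste0("correlation matrix of subject '", subject, "'")
  .check_square_symmetric(C, who)
  d <- nrow(C)
  if (d < 2) stop(who, " must be at least 2x2", call. = FALSE)
  if (max(abs(diag(C) - 1)) > .tol("unit_diagonal")) {
    stop(who, " does not have unit diagonal", call. = FALSE)
  }
  if (max(abs(C)) > 1 + .tol("correlation_range")) {
    stop(who, " has entries outside [-1, 1]", call. = FALSE)
  }
  ev_min <- min(eigen(.symmetrize(C), symmetric = TRUE,
                      only.values = TRUE)$values)
  if (ev_min < -.tol("psd")) {
    stop(who, " is not positive semidefinite (min eigenvalue ",
         format(ev_min), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Regularize a correlation matrix onto the SPD cone
#'
#' Correlation matrices can have zero eigenvalues; `P = C + mu * I` with a
#' small `mu > 0` makes them strictly positive definite.  If the result is
#' still numerically singular, `mu` is escalated by factors of 10 up to
#' `1e-4` before giving up.
#'
#' @param C Correlation matrix (validated with [check_correlation()]).
#' @param mu Positive regularization constant (default `1e-10`).
#' @param subject Optional subject id for error messages.
#' @return The SPD matrix `C + mu * I` (for the smallest sufficient `mu`).
#' @examples
#' regularize(diag(2), mu = 1e-10)
#' @export
regularize <- function(C, mu = 1e-10, subject = NULL) {
  stopifnot(is.numeric(mu), length(mu) == 1, mu > 0)
  check_correlation(C, subject)
  C <- .symmetrize(C)
  mu_try <- mu
  repeat {
    P <- C + diag(mu_try, nrow(C))
    ev_min <- min(eigen(P, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min > 0) return(P)
    if (mu_try >= 1e-4) break
    mu_try <- mu_try * 10
  }
  who <- if (is.null(subject)) "input" else paste0("subject '", subject, "'")
  stop("degenerate input: ", who,
       " is not positive definite even with mu = 1e-4", call. = FALSE)
}

.spd_eigen <- function(P, what = "SPD matrix") {
  .check_square_symmetric(P, what)
  e <- eigen(.symmetrize(P), symmetric = TRUE)
  if (min(e$values) <= 0) {
    stop(what, " has a non-positive eigenvalue (",
         format(min(e$values)), "); not on the SPD cone", call. = FALSE)
  }
  e
}

#' Principal matrix logarithm of an SPD matrix
#'
#' Maps a point on the SPD cone to its log-coordinates, the tangent space
#' at the identity.  Computed as `U diag(log lambda) U'` from the
#' symmetric eigendecomposition.
#'
#' @param P SPD matrix.
#' @return Symmetric matrix `log(P)`.
#' @export
matrix_log <- function(P) {
  e <- .spd_eigen(P)
  .symmetrize(e$vectors %*% (log(e$values) * t(e$vectors)))
}

#' Matrix exponential of a symmetric matrix
#'
#' Inverse of [matrix_log()]: maps log-coordinates back onto the SPD cone.
#' The result is always symmetric positive definite.
#'
#' @param S Symmetric matrix.
#' @return SPD matrix `exp(S)`.
#' @export
matrix_exp <- function(S) {
  .check_square_symmetric(S, "tangent matrix")
  e <- eigen(.symmetrize(S), symmetric = TRUE)
  .symmetrize(e$vectors %*% (exp(e$values) * t(e$vectors)))
}

#' Log-Euclidean geodesic distance between two SPD matrices
#'
#' `d(P, Q) = || log(Q) - log(P) ||_F`.  This is a true metric on the SPD
#' cone: symmetric, zero iff `P == Q`, and satisfying the triangle
#' inequality, and it is invariant under orthogonal congruence and under
#' joint matrix inversion.
#'
#' @param P,Q SPD matrices of equal dimension.
#' @return Non-negative scalar distance.
#' @export
log_euclidean_distance <- function(P, Q) {
  norm(tangent_at_identity(P, Q), type = "F")
}

#' Tangent matrix at the identity encoding the geodesic from P to Q
#'
#' The geodesic from `P` to `Q` is encoded by a tangent matrix in the
#' tangent space at `P`; under the Log-Euclidean metric its parallel
#' translation to the tangent space at the identity is simply
#' `log(Q) - log(P)` (transport is path-independent translation in
#' log-coordinates).  Its Frobenius norm equals the geodesic distance, and
#' swapping the arguments negates it.
#'
#' @param P,Q SPD matrices of equal dimension.
#' @return Symmetric matrix `log(Q) - log(P)`.
#' @export
tangent_at_identity <- function(P, Q) {
  if (!is.matrix(P) || !is.matrix(Q) || !all(dim(P) == dim(Q))) {
    stop("P and Q must be matrices of identical dimension", call. = FALSE)
  }
  matrix_log(Q) - matrix_log(P)
}
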