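#' Numerical tolerances used across the package
#'
#' Single place for the validation and convergence tolerances used by the
#' geometry, feature and model code.
#'
#' @return Named list of tolerances:
#' \describe{
#'   \item{symmetry}{maximum allowed asymmetry \eqn{\max|M - M^T|}}
#'   \item{unit_diagonal}{maximum deviation of correlation diagonals from 1}
#'   \item{correlation_range}{slack on the \eqn{[-1, 1]} entry bound}
#'   \item{psd}{how negative the smallest eigenvalue of a correlation
#'     matrix may be before it is rejected}
#'   \item{power_iteration}{convergence tolerance for eigenvector
#'     centrality}
#' }
#' @export
reggnn_tolerances <- function() {
  list(
    symmetry          = 1e-8,
    unit_diagonal     = 1e-6,
    correlation_range = 1e-9,
    psd               = 1e-8,
    power_iteration   = 1e-10
  )
}

.tol <- function(name) reggnn_tolerances()[[name]]
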