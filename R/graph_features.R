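#' Graph-topological features of tangent matrices
#'
#' @description
#' A tangent matrix represents the linearized difference between two
#' connectomes; its entries are signed.  To compress it into a compact
#' descriptor for the difference regressor, it is read as a weighted graph
#' whose edge weights are the absolute off-diagonal entries (the magnitude
#' of the connectivity change; the diagonal is treated as absent), and
#' node centralities are computed on that graph.
#'
#' Eight feature modes are supported:
#' \describe{
#'   \item{tm}{row-major upper triangle (including the diagonal) of the
#'     tangent matrix, length \eqn{d(d+1)/2}}
#'   \item{dc, ec, cc}{degree / eigenvector / closeness centrality of the
#'     tangent matrix, length \eqn{d}}
#'   \item{cnu}{concatenation `c(dc, ec, cc)`, unscaled, length \eqn{3d}}
#'   \item{cns}{the same concatenation with each block min-max scaled to
#'     \eqn{[0, 1]} first}
#'   \item{g}{scalar Log-Euclidean geodesic distance}
#'   \item{a}{scalar Euclidean distance between the upper-triangular parts
#'     of the two SPD matrices themselves (the non-geometric baseline)}
#' }
#'
#' @name graph_features
NULL

#' Supported feature modes
#'
#' @return Character vector of the eight feature mode codes.
#' @export
feature_modes <- function() c("tm", "dc", "ec", "cc", "cnu", "cns", "g", "a")

#' Length of a feature vector for a given mode and graph size
#'
#' @param mode One of [feature_modes()].
#' @param d Number of nodes (ROIs).
#' @return Integer feature length.
#' @export
feature_length <- function(mode, d) {
  mode <- match.arg(mode, feature_modes())
  switch(mode,
    tm  = d * (d + 1) / 2,
    dc  = ,
    ec  = ,
    cc  = d,
    cnu = ,
    cns = 3 * d,
    g   = ,
    a   = 1L
  )
}

.abs_weights <- function(W) {
  .check_square_symmetric(W, "tangent matrix")
  if (nrow(W) < 2) stop("graph must have at least 2 nodes", call. = FALSE)
  A <- abs(W)
  diag(A) <- 0
  A
}

#' Weighted degree centrality
#'
#' Node `i` scores the mean absolute edge weight to the other `d - 1`
#' nodes: `sum_j |W_ij| / (d - 1)` over `j != i`.
#'
#' @param W Symmetric matrix read as a weighted graph (absolute
#'   off-diagonal entries are the edge weights).
#' @return Numeric vector of length `d`.
#' @export
degree_centrality <- function(W) {
  A <- .abs_weights(W)
  rowSums(A) / (nrow(A) - 1)
}

#' Eigenvector centrality by power iteration
#'
#' Principal eigenvector of the absolute-weight matrix, normalized to unit
#' Euclidean norm with non-negative entries.  The iteration runs on
#' `A + I`: the spectral shift leaves eigenvectors unchanged but
#' guarantees convergence on bipartite-like graphs where iterating on `A`
#' itself oscillates.
#'
#' @param W Symmetric matrix read as a weighted graph.
#' @param tol Convergence tolerance on successive iterates.
#' @param max_iter Iteration cap.
#' @return Numeric vector of length `d`, non-negative, unit norm.
#' @export
eigenvector_centrality <- function(W, tol = .tol("power_iteration"),
                                   max_iter = 1000L) {
  A <- .abs_weights(W)
  if (all(A == 0)) {
    stop("degenerate input: graph has no edges", call. = FALSE)
  }
  d <- nrow(A)
  M <- A + diag(1, d)
  x <- rep(1 / sqrt(d), d)
  for (it in seq_len(max_iter)) {
    y <- as.vector(M %*% x)
    y <- y / sqrt(sum(y^2))
    if (max(abs(y - x)) < tol) {
      y <- abs(y)
      return(y / sqrt(sum(y^2)))
    }
    x <- y
  }
  stop("eigenvector centrality did not converge in ", max_iter,
       " iterations", call. = FALSE)
}

#' Weighted closeness centrality (Wasserman-Faust scaled)
#'
#' An edge exists wherever `|W_ij| > 0`, with length `1 / |W_ij|`
#' (stronger connectivity change = shorter distance).  Node `i` scores
#' `(r_i / (d - 1)) * (r_i / sum of shortest-path lengths to reachable
#' nodes)` where `r_i` counts nodes reachable from `i`; for a connected
#' graph this is the classic `(d - 1) / sum_j delta(i, j)`.  Isolated
#' nodes score 0.  Shortest paths are computed with
#' [igraph::distances()].
#'
#' @param W Symmetric matrix read as a weighted graph.
#' @return Numeric vector of length `d`.
#' @export
closeness_centrality <- function(W) {
  A <- .abs_weights(W)
  d <- nrow(A)
  L <- ifelse(A > 0, 1 / A, 0)
  g <- igraph::graph_from_adjacency_matrix(L, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  D <- igraph::distances(g, algorithm = "dijkstra")
  vapply(seq_len(d), function(i) {
    reach <- is.finite(D[i, ]) & seq_len(d) != i
    r <- sum(reach)
    if (r == 0) return(0)
    (r / (d - 1)) * (r / sum(D[i, reach]))
  }, numeric(1))
}

#' Min-max scale a vector to [0, 1]
#'
#' `(v - min) / (max - min)`; a constant vector maps to all zeros (the
#' 0/0 case is defined away).
#'
#' @param v Non-empty numeric vector.
#' @return Vector of the same length with entries in \eqn{[0, 1]}.
#' @export
minmax_scale <- function(v) {
  stopifnot(is.numeric(v), length(v) >= 1)
  rng <- range(v)
  if (rng[1] == rng[2]) return(rep(0, length(v)))
  (v - rng[1]) / (rng[2] - rng[1])
}

# row-major upper triangle (incl. diagonal); for a symmetric matrix this
# equals the column-major lower triangle
.upper_tri_vec <- function(M) M[lower.tri(M, diag = TRUE)]

# core feature computation given precomputed log-matrices (Li, Lj) and,
# for mode "a", the SPD matrices themselves
.pair_features_log <- function(Li, Lj, mode, Pi = NULL, Pj = NULL) {
  S <- Lj - Li
  switch(mode,
    tm  = .upper_tri_vec(S),
    dc  = degree_centrality(S),
    ec  = eigenvector_centrality(S),
    cc  = closeness_centrality(S),
    cnu = c(degree_centrality(S), eigenvector_centrality(S),
            closeness_centrality(S)),
    cns = c(minmax_scale(degree_centrality(S)),
            minmax_scale(eigenvector_centrality(S)),
            minmax_scale(closeness_centrality(S))),
    g   = norm(S, type = "F"),
    a   = sqrt(sum((.upper_tri_vec(Pi) - .upper_tri_vec(Pj))^2))
  )
}

#' Feature vector for a pair of SPD connectomes
#'
#' Computes the pairwise difference descriptor used by the sample
#' selection regressor.  All modes except `tm` are symmetric in the two
#' arguments; `tm` negates under a swap (the tangent matrix is oriented).
#'
#' @param P_i,P_j SPD matrices of equal dimension (regularized
#'   connectomes).
#' @param mode One of [feature_modes()].
#' @return Numeric vector of length `feature_length(mode, d)`.
#' @examples
#' P <- diag(2)
#' Q <- diag(c(exp(3), exp(-4)))
#' extract_pair_features(P, Q, "g")  # 5
#' @export
extract_pair_features <- function(P_i, P_j, mode) {
  mode <- match.arg(mode, feature_modes())
  if (!all(dim(P_i) == dim(P_j))) {
    stop("P_i and P_j must have identical dimension", call. = FALSE)
  }
  .pair_features_log(matrix_log(P_i), matrix_log(P_j), mode,
                     Pi = P_i, Pj = P_j)
}
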