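#' Synthetic connectome cohorts with planted structure
#'
#' @description
#' Generates desk-scale cohorts of correlation-matrix connectomes with
#' known ground truth, so selection and regression can be validated
#' without any imaging data.  Generation happens in log-matrix
#' coordinates: each cluster gets a center log-matrix, each subject a
#' symmetric perturbation of its cluster center, and the result is
#' exponentiated back onto the SPD cone and rescaled to unit diagonal.
#' Because the cluster geometry is planted in exactly the log-coordinates
#' the Log-Euclidean selection machinery works in, recovery tests have a
#' meaningful ground truth.  (The unit-diagonal rescaling slightly
#' distorts the planted geometry; all invariants are checked after
#' rescaling.)
#'
#' Scores can be coupled to the connectomes in three ways:
#' `"cluster_only"` (score = cluster center + noise; isotropic log-space
#' perturbations), `"linear_in_tangent"` (within-cluster deviations lie
#' along one shared tangent direction and the score depends linearly on
#' the coordinate along it, so pairwise difference features are exactly
#' proportional to within-cluster score differences — the regime the
#' selection regressor assumes; the direction and coordinates are
#' recorded in the ground truth), or `"pure_noise"` (scores independent
#' of the connectomes).
#'
#' @name synthetic_cohort
NULL

#' Cohort specification
#'
#' Default score statistics emulate a neurotypical full-scale IQ
#' distribution (mean approximately 111.6, sd approximately 12), split
#' over three clusters at mean and one standard deviation either side.
#'
#' @param n_subjects Number of subjects.
#' @param d Matrix dimension (ROIs).
#' @param n_clusters Number of planted clusters.
#' @param within_cluster_sd Entrywise sd of the log-matrix perturbation
#'   around the cluster center (log-matrix Frobenius units).
#' @param score_centers Numeric vector of per-cluster score centers (IQ
#'   points); length `n_clusters`.
#' @param score_sd Independent score noise sd (IQ points).
#' @param coupling `"cluster_only"`, `"linear_in_tangent"` or
#'   `"pure_noise"`.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param between_cluster_sd Entrywise sd of the cluster-center
#'   log-matrices (controls cluster separation; default 1).
#' @param coupling_score_sd Under `"linear_in_tangent"`, the sd of the
#'   linear tangent-feature contribution to the score, i.e. the
#'   within-cluster score spread it induces (default 0.1 IQ points).
#' @param mu Regularization constant for the subjects.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 60L, d = 30L, n_clusters = 3L,
                        within_cluster_sd = 0.3,
                        score_centers = c(99.5, 111.6, 123.6),
                        score_sd = 4, coupling = c("cluster_only",
                                                   "linear_in_tangent",
                                                   "pure_noise"),
                        seed = 1L, between_cluster_sd = 1,
                        coupling_score_sd = 0.1, mu = 1e-10) {
  coupling <- match.arg(coupling)
  stopifnot(n_subjects >= 1, d >= 2, n_clusters >= 1,
            n_clusters <= n_subjects, within_cluster_sd >= 0,
            score_sd >= 0, length(score_centers) == n_clusters,
            between_cluster_sd > 0, coupling_score_sd >= 0, mu > 0)
  structure(
    list(n_subjects = as.integer(n_subjects), d = as.integer(d),
         n_clusters = as.integer(n_clusters),
         within_cluster_sd = within_cluster_sd,
         score_centers = score_centers, score_sd = score_sd,
         coupling = coupling, seed = as.integer(seed),
         between_cluster_sd = between_cluster_sd,
         coupling_score_sd = coupling_score_sd, mu = mu),
    class = "cohort_spec"
  )
}

# symmetric matrix with iid N(0, sd) entries on the upper triangle
# (incl. diagonal), mirrored
.random_symmetric <- function(d, sd = 1) {
  S <- matrix(0, d, d)
  S[lower.tri(S, diag = TRUE)] <- stats::rnorm(d * (d + 1) / 2, sd = sd)
  S[upper.tri(S)] <- t(S)[upper.tri(S)]
  S
}

# exp(L) rescaled to unit diagonal; clamp fp noise outside [-1, 1]
.log_to_correlation <- function(L) {
  S <- matrix_exp(L)
  R <- stats::cov2cor(S)
  R <- .symmetrize(R)
  diag(R) <- 1
  R[R > 1] <- 1
  R[R < -1] <- -1
  R
}

#' Draw a random correlation matrix
#'
#' Draws a random symmetric log-matrix and maps it through the matrix
#' exponential and unit-diagonal rescaling, so the result is a valid
#' (strictly positive definite) correlation matrix.  Uses the current
#' RNG state; seed outside if reproducibility is needed.
#'
#' @param d Dimension (at least 2).
#' @param log_sd Entrywise sd of the log-matrix (default 0.3).
#' @return d x d correlation matrix.
#' @export
make_random_correlation <- function(d, log_sd = 0.3) {
  stopifnot(d >= 2)
  .log_to_correlation(.random_symmetric(d, log_sd))
}

#' Generate a synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `synthetic_cohort`: list with `subjects` (list
#'   of [make_subject()] objects, ids `s001`, `s002`, ...),
#'   `ground_truth` (per subject: cluster label, tangent coordinate `z`
#'   and deviation log-matrix), and `direction` (the shared tangent
#'   direction under `linear_in_tangent`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    d <- spec$d
    cluster_of <- rep(seq_len(spec$n_clusters),
                      length.out = spec$n_subjects)
    centers <- lapply(seq_len(spec$n_clusters), function(c) {
      .random_symmetric(d, spec$between_cluster_sd)
    })
    direction <- NULL
    if (spec$coupling == "linear_in_tangent") {
      # one shared tangent direction, unit Frobenius norm: subjects sit
      # on a line in log-coordinates, so any feature that is homogeneous
      # in the tangent matrix is exactly proportional to |score_i -
      # score_j| within a cluster
      direction <- .random_symmetric(d, 1)
      direction <- direction / norm(direction, type = "F")
    }
    subjects <- vector("list", spec$n_subjects)
    ground_truth <- vector("list", spec$n_subjects)
    for (i in seq_len(spec$n_subjects)) {
      cl <- cluster_of[i]
      if (spec$coupling == "linear_in_tangent") {
        z <- stats::rnorm(1)
        dev <- z * spec$within_cluster_sd * direction
      } else {
        z <- NA_real_
        dev <- .random_symmetric(d, 1) * spec$within_cluster_sd
      }
      L <- centers[[cl]] + dev
      C <- .log_to_correlation(L)
      score <- switch(spec$coupling,
        cluster_only = spec$score_centers[cl] +
          stats::rnorm(1, sd = spec$score_sd),
        linear_in_tangent = spec$score_centers[cl] +
          spec$coupling_score_sd * z + stats::rnorm(1, sd = spec$score_sd),
        pure_noise = mean(spec$score_centers) +
          stats::rnorm(1, sd = spec$score_sd)
      )
      id <- sprintf("s%03d", i)
      subjects[[i]] <- make_subject(id, C, score, mu = spec$mu)
      ground_truth[[i]] <- list(id = id, cluster = cl, coordinate = z,
                                deviation = dev)
    }
    names(ground_truth) <- vapply(ground_truth, `[[`, character(1), "id")
    structure(
      list(subjects = subjects, ground_truth = ground_truth,
           direction = direction, spec = spec),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic cohort: ", length(x$subjects), " subjects, d = ",
      x$spec$d, ", ", x$spec$n_clusters, " clusters, coupling = ",
      x$spec$coupling, ">\n", sep = "")
  invisible(x)
}

#' Write a cohort in the pipeline's input format
#'
#' One whitespace-delimited matrix file per subject (named `<id>.txt`)
#' plus a `scores.csv` table with columns `id,FIQ,VIQ` (both score
#' columns carry the single generated score).
#'
#' @param cohort A `synthetic_cohort` (or plain list of subjects).
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  subjects <- if (inherits(cohort, "synthetic_cohort")) cohort$subjects
              else cohort
  .check_cohort(subjects)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in subjects) {
    utils::write.table(
      format(s$connectome, digits = 17, scientific = TRUE, trim = TRUE),
      file.path(dir, paste0(s$id, ".txt")),
      sep = " ", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
  }
  scores <- data.frame(
    id = .subject_ids(subjects),
    FIQ = .subject_scores(subjects),
    VIQ = .subject_scores(subjects)
  )
  utils::write.csv(scores, file.path(dir, "scores.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}
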