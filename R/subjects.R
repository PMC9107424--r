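#' Subjects and cohorts
#'
#' A subject bundles an id, its raw connectome (correlation matrix), the
#' regularized SPD version, its log-matrix (cached, since every pairwise
#' tangent matrix is a difference of two log-matrices), and the scalar
#' cognitive score.  A cohort is a list of subjects sharing one matrix
#' dimension.
#'
#' @name subjects
NULL

#' Construct a subject
#'
#' Validates the connectome, regularizes it onto the SPD cone and caches
#' its matrix logarithm.
#'
#' @param id Subject identifier (character scalar).
#' @param connectome d x d correlation matrix.
#' @param score Scalar cognitive score (IQ points).
#' @param mu Regularization constant passed to [regularize()].
#' @return Object of class `reggnn_subject` with fields `id`,
#'   `connectome`, `spd`, `logm`, `score`, `mu`.
#' @export
make_subject <- function(id, connectome, score, mu = 1e-10) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  if (!is.numeric(score) || length(score) != 1 || !is.finite(score)) {
    stop("subject '", id, "' has a missing or non-finite score",
         call. = FALSE)
  }
  spd <- regularize(connectome, mu = mu, subject = id)
  structure(
    list(id = id, connectome = connectome, spd = spd,
         logm = matrix_log(spd), score = score, mu = mu),
    class = "reggnn_subject"
  )
}

#' @export
print.reggnn_subject <- function(x, ...) {
  cat("<subject ", x$id, ": ", nrow(x$spd), " ROIs, score ",
      format(x$score), ">\n", sep = "")
  invisible(x)
}

.check_cohort <- function(subjects, min_n = 1) {
  if (!is.list(subjects) || length(subjects) < min_n ||
      !all(vapply(subjects, inherits, logical(1), "reggnn_subject"))) {
    stop("expected a list of at least ", min_n, " subjects", call. = FALSE)
  }
  ids <- vapply(subjects, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate subject ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  ds <- vapply(subjects, function(s) nrow(s$spd), integer(1))
  if (length(unique(ds)) != 1) {
    stop("subjects have differing matrix dimensions: ",
         paste(unique(ds), collapse = ", "), call. = FALSE)
  }
  invisible(ids)
}

.subject_ids <- function(subjects) {
  vapply(subjects, `[[`, character(1), "id")
}

.subject_scores <- function(subjects) {
  vapply(subjects, `[[`, numeric(1), "score")
}
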