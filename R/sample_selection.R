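#' Learning-based selection of predictive training samples
#'
#' @description
#' Rather than training the regression network on every available
#' subject, the k most predictive training samples are identified first.
#' The idea: if similar connectomes map to similar scores, then a linear
#' map `f` from pairwise connectome-difference features to absolute score
#' differences can be learned, and the training subjects that `f`
#' consistently places closest (in predicted score) to held-out subjects
#' are the most representative of the cohort.
#'
#' The procedure runs inside the training set only, in a nested N-fold
#' cross-validation.  Each fold splits the training set into a train-in
#' group and a holdout group, then:
#' \enumerate{
#'   \item tangent matrices at the identity are derived for every
#'     train-in pair and every train-in/holdout pair;
#'   \item each tangent matrix is compressed into a feature vector
#'     (see [extract_pair_features()]);
#'   \item a linear regressor `f` is fit on train-in pair features against
#'     absolute score differences;
#'   \item for each holdout subject, the k train-in subjects with the
#'     smallest predicted difference get their frequency counter
#'     incremented.
#' }
#' After all N folds, the k subjects with the highest cumulative
#' frequency are selected (ties broken by ascending id).
#'
#' @name sample_selection
NULL

#' Configuration for sample selection
#'
#' @param k Number of samples to select (the study varies k from 2 to 15;
#'   values outside that range are allowed but flagged).
#' @param n_folds Number N of inner cross-validation folds (default 5).
#' @param mode Feature mode, one of [feature_modes()] (default `"dc"`).
#' @param seed Integer seed controlling the fold shuffle.
#' @param mu Regularization constant (recorded; subjects carry their own).
#' @return Object of class `selection_config`.
#' @export
selection_config <- function(k = 5L, n_folds = 5L, mode = "dc",
                             seed = 1L, mu = 1e-10) {
  mode <- match.arg(mode, feature_modes())
  stopifnot(k >= 1, n_folds >= 2, mu > 0)
  structure(
    list(k = as.integer(k), n_folds = as.integer(n_folds), mode = mode,
         seed = as.integer(seed), mu = mu),
    class = "selection_config"
  )
}

#' Fit the linear difference regressor
#'
#' Ordinary least squares with intercept, via column centering and an SVD
#' pseudoinverse.  When the feature dimension exceeds the number of pairs
#' (possible for the `tm` mode), this returns the minimum-norm
#' least-squares solution.
#'
#' @param X Numeric matrix, one row per pair.
#' @param y Numeric vector of absolute score differences.
#' @return Object of class `difference_regressor` with `coefficients` and
#'   `intercept`.
#' @export
fit_difference_regressor <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 pairs to fit", call. = FALSE)
  if (length(y) != nrow(X)) stop("X and y lengths differ", call. = FALSE)
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  sv <- svd(Xc)
  tol <- max(dim(Xc)) * .Machine$double.eps * max(sv$d, 0)
  keep <- sv$d > tol
  coef <- if (!any(keep)) {
    rep(0, ncol(X))
  } else {
    drop(sv$v[, keep, drop = FALSE] %*%
           (crossprod(sv$u[, keep, drop = FALSE], y - ym) / sv$d[keep]))
  }
  structure(
    list(coefficients = coef, intercept = ym - sum(coef * xm)),
    class = "difference_regressor"
  )
}

#' @param object A `difference_regressor`.
#' @param newdata Matrix (or vector, taken as one row per element for
#'   1-feature models) of features.
#' @param ... Unused.
#' @rdname fit_difference_regressor
#' @export
predict.difference_regressor <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, ncol = length(object$coefficients))
  drop(newdata %*% object$coefficients + object$intercept)
}

# feature rows for all unordered train-in pairs (i < j, list order) and
# the matching |score_i - score_j| targets
.train_in_pairs <- function(train_in, mode) {
  n <- length(train_in)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  feats <- lapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1]; j <- idx[r, 2]
    .pair_features_log(train_in[[i]]$logm, train_in[[j]]$logm, mode,
                       Pi = train_in[[i]]$spd, Pj = train_in[[j]]$spd)
  })
  scores <- .subject_scores(train_in)
  list(
    X = do.call(rbind, feats),
    y = abs(scores[idx[, 2]] - scores[idx[, 1]])
  )
}

# n_train x n_holdout matrix of predicted absolute score differences
.selection_fold_predictions <- function(train_in, holdout, mode) {
  pairs <- .train_in_pairs(train_in, mode)
  f <- fit_difference_regressor(pairs$X, pairs$y)
  cross <- lapply(holdout, function(h) {
    do.call(rbind, lapply(train_in, function(s) {
      .pair_features_log(s$logm, h$logm, mode, Pi = s$spd, Pj = h$spd)
    }))
  })
  vapply(cross, function(Xh) predict(f, Xh), numeric(length(train_in)))
}

# top-k increments given the prediction matrix; ties by ascending id
.increments_from_predictions <- function(pred, train_ids, k) {
  counts <- stats::setNames(integer(length(train_ids)), train_ids)
  for (col in seq_len(ncol(pred))) {
    top <- order(pred[, col], train_ids)[seq_len(k)]
    counts[top] <- counts[top] + 1L
  }
  counts
}

#' Run one selection fold
#'
#' Fits the difference regressor on the train-in group and, for each
#' holdout subject, increments the k train-in subjects with the smallest
#' predicted absolute score difference.
#'
#' @param train_in,holdout Disjoint lists of subjects (see
#'   [make_subject()]).
#' @param cfg A [selection_config()].
#' @return Named integer vector of increments (names = train-in ids);
#'   sums to `k * length(holdout)`.
#' @export
run_selection_fold <- function(train_in, holdout, cfg) {
  stopifnot(inherits(cfg, "selection_config"))
  .check_cohort(c(train_in, holdout), min_n = 3)
  if (cfg$k > length(train_in)) {
    stop("k = ", cfg$k, " exceeds train-in group size ",
         length(train_in), call. = FALSE)
  }
  pred <- .selection_fold_predictions(train_in, holdout, cfg$mode)
  .increments_from_predictions(pred, .subject_ids(train_in), cfg$k)
}

# near-equal fold assignment: sizes differ by at most 1, remainder going
# to the first folds; positions are pre-shuffled by the caller
.fold_assignment <- function(n, n_folds) {
  base <- n %/% n_folds
  extra <- n %% n_folds
  rep(seq_len(n_folds), times = base + (seq_len(n_folds) <= extra))
}

#' Select the k most predictive training samples
#'
#' Runs the full nested N-fold procedure: a seeded shuffle of subject
#' positions, near-equal folds, one [run_selection_fold()] per fold with
#' that fold as holdout, and accumulation of the frequency map.  Each
#' subject is in the train-in group exactly N - 1 times.
#'
#' @param training_set List of subjects.
#' @param cfg A [selection_config()].
#' @param ks Optional integer vector of k values to sweep; fold
#'   predictions are shared across the sweep.  Defaults to `cfg$k`.
#' @return Object of class `selection_result` with fields `selected_ids`
#'   (for `cfg$k`, or a named list when sweeping), `frequency` (named
#'   integer vector over all subjects, ascending id), `per_fold_log`, and
#'   the configuration.  When sweeping, `selected_by_k` maps each k to its
#'   selected ids and `frequency_by_k` to its frequency map.
#' @export
select_samples <- function(training_set, cfg, ks = NULL) {
  stopifnot(inherits(cfg, "selection_config"))
  ids <- .check_cohort(training_set, min_n = cfg$n_folds)
  n <- length(training_set)
  if (is.null(ks)) ks <- cfg$k
  ks <- sort(unique(as.integer(ks)))

  perm <- withr::with_seed(cfg$seed, sample.int(n))
  fold_of <- .fold_assignment(n, cfg$n_folds)
  # smallest train-in size across folds bounds k
  min_train_in <- n - max(tabulate(fold_of, cfg$n_folds))
  if (max(ks) > min_train_in) {
    stop("k = ", max(ks), " exceeds the smallest train-in group size (",
         min_train_in, ")", call. = FALSE)
  }

  counts_by_k <- lapply(ks, function(k) {
    stats::setNames(integer(n), sort(ids))
  })
  names(counts_by_k) <- as.character(ks)
  per_fold_log <- vector("list", cfg$n_folds)

  for (fold in seq_len(cfg$n_folds)) {
    hold_pos <- perm[fold_of == fold]
    train_pos <- perm[fold_of != fold]
    train_in <- training_set[train_pos]
    holdout <- training_set[hold_pos]
    pred <- .selection_fold_predictions(train_in, holdout, cfg$mode)
    train_ids <- .subject_ids(train_in)
    fold_inc <- list()
    for (kk in as.character(ks)) {
      inc <- .increments_from_predictions(pred, train_ids, as.integer(kk))
      counts_by_k[[kk]][names(inc)] <- counts_by_k[[kk]][names(inc)] + inc
      fold_inc[[kk]] <- inc
    }
    per_fold_log[[fold]] <- list(
      fold = fold,
      holdout_ids = .subject_ids(holdout),
      increments = if (length(ks) == 1) fold_inc[[1]] else fold_inc
    )
  }

  top_k <- function(counts, k) {
    ord <- order(-counts, names(counts))
    sort(names(counts)[ord[seq_len(k)]])
  }
  selected_by_k <- Map(top_k, counts_by_k, ks)
  names(selected_by_k) <- as.character(ks)

  structure(
    list(
      selected_ids = selected_by_k[[as.character(cfg$k %||% ks[1])]] %||%
        selected_by_k[[1]],
      selected_by_k = selected_by_k,
      frequency = counts_by_k[[as.character(cfg$k)]] %||% counts_by_k[[1]],
      frequency_by_k = counts_by_k,
      per_fold_log = per_fold_log,
      config = cfg,
      ks = ks
    ),
    class = "selection_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection: k =", x$config$k, ", N =", x$config$n_folds,
      ", mode =", x$config$mode, ">\n")
  cat("selected:", paste(x$selected_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Write a selection report table
#'
#' One row per training subject: id, cumulative frequency, and whether it
#' was selected.
#'
#' @param result A `selection_result`.
#' @param path Output file (tab-separated).
#' @return The report `data.frame`, invisibly.
#' @export
write_selection_report <- function(result, path) {
  stopifnot(inherits(result, "selection_result"))
  df <- data.frame(
    id = names(result$frequency),
    frequency = as.integer(result$frequency),
    selected = names(result$frequency) %in% result$selected_ids,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}
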