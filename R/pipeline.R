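#' End-to-end evaluation pipeline
#'
#' @description
#' Orchestrates the full training process: (A) an outer train/test split
#' by k-fold cross-validation, (B) learning-based sample selection run
#' only inside each training split, and (C) RegGNN trained on the k
#' selected subjects and evaluated on the untouched test split, swept
#' over a range of k and compared against a baseline trained on all
#' training samples (and a mean-predictor null).  One master seed derives
#' the split, selection and model seeds by fixed offsets, so every
#' component is independently reproducible.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param outer_folds Number of outer cross-validation folds (default 3).
#' @param selection A [selection_config()] (its `k` is ignored; the sweep
#'   drives k).
#' @param model A [reggnn_config()]; `d` is taken from the data at run
#'   time.
#' @param k_sweep Integer vector of k values (default `2:15`).
#' @param score_column Which score column to use from the scores table
#'   (`"FIQ"` or `"VIQ"`).
#' @param seed Master seed.
#' @param output_dir Optional directory; when set, [run_pipeline()]
#'   writes the report files there.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(outer_folds = 3L,
                            selection = selection_config(),
                            model = reggnn_config(),
                            k_sweep = 2:15,
                            score_column = c("FIQ", "VIQ"),
                            seed = 1L, output_dir = NULL) {
  score_column <- match.arg(score_column)
  stopifnot(outer_folds >= 2, length(k_sweep) >= 1, all(k_sweep >= 1))
  structure(
    list(outer_folds = as.integer(outer_folds), selection = selection,
         model = model, k_sweep = sort(unique(as.integer(k_sweep))),
         score_column = score_column, seed = as.integer(seed),
         output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' Load a cohort from disk
#'
#' Reads one whitespace-delimited d x d matrix per subject from
#' `matrix_dir` (file name without extension = subject id) and a scores
#' CSV with header `id,FIQ,VIQ`.  Every matrix must be square of one
#' common dimension and every subject must have a finite score; failures
#' are reported per file.
#'
#' @param matrix_dir Directory of per-subject matrix files.
#' @param scores_file CSV path.
#' @param score_column `"FIQ"` or `"VIQ"`.
#' @param mu Regularization constant.
#' @return List of subjects sorted by id.
#' @export
load_cohort <- function(matrix_dir, scores_file,
                        score_column = c("FIQ", "VIQ"), mu = 1e-10) {
  score_column <- match.arg(score_column)
  if (!dir.exists(matrix_dir)) stop("no such directory: ", matrix_dir, call. = FALSE)
  files <- sort(list.files(matrix_dir, pattern = "\\.(txt|tsv|csv|mat)$",
                           full.names = TRUE))
  files <- files[basename(files) != "scores.csv"]
  if (length(files) == 0) stop("no matrix files in ", matrix_dir, call. = FALSE)
  scores <- utils::read.csv(scores_file, stringsAsFactors = FALSE)
  if (!all(c("id", score_column) %in% names(scores))) {
    stop("scores table must have columns 'id' and '", score_column, "'",
         call. = FALSE)
  }
  problems <- character()
  subjects <- list()
  for (f in files) {
    id <- sub("\\.[^.]+$", "", basename(f))
    M <- tryCatch(as.matrix(utils::read.table(f)), error = function(e) e)
    if (inherits(M, "error")) {
      problems <- c(problems, paste0(f, ": unreadable (", conditionMessage(M), ")"))
      next
    }
    dimnames(M) <- NULL
    if (nrow(M) != ncol(M)) {
      problems <- c(problems, paste0(f, ": non-square matrix ",
                                     nrow(M), "x", ncol(M)))
      next
    }
    if (anyNA(M)) {
      problems <- c(problems, paste0(f, ": contains NA entries"))
      next
    }
    row <- match(id, scores$id)
    if (is.na(row) || !is.finite(scores[[score_column]][row])) {
      problems <- c(problems, paste0(f, ": no ", score_column,
                                     " score for id '", id, "'"))
      next
    }
    s <- tryCatch(make_subject(id, M, scores[[score_column]][row], mu = mu),
                  error = function(e) e)
    if (inherits(s, "error")) {
      problems <- c(problems, paste0(f, ": ", conditionMessage(s)))
      next
    }
    subjects[[id]] <- s
  }
  if (length(problems) > 0) {
    stop("cohort loading failed:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  .check_cohort(subjects)
  unname(subjects[order(names(subjects))])
}

#' Seeded k-fold split
#'
#' @param n Number of items.
#' @param folds Number of folds.
#' @param seed Integer seed for the shuffle.
#' @return List of `folds` elements, each `list(train = , test = )` with
#'   disjoint, exhaustive, near-equal index vectors.
#' @export
kfold_split <- function(n, folds, seed) {
  if (folds > n) stop("more folds (", folds, ") than items (", n, ")",
                      call. = FALSE)
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  fold_of <- .fold_assignment(n, folds)
  lapply(seq_len(folds), function(f) {
    list(train = sort(perm[fold_of != f]), test = sort(perm[fold_of == f]))
  })
}

#' Mean absolute error
#' @param pred,truth Numeric vectors of equal nonzero length.
#' @return Scalar MAE.
#' @export
compute_mae <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) == 0) {
    stop("pred and truth must have equal nonzero length", call. = FALSE)
  }
  mean(abs(pred - truth))
}

#' Root mean squared error
#' @rdname compute_mae
#' @export
compute_rmse <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) == 0) {
    stop("pred and truth must have equal nonzero length", call. = FALSE)
  }
  sqrt(mean((pred - truth)^2))
}

#' Welch two-sample t-test p-value
#'
#' Two-sided p-value comparing two sets of absolute errors, using the
#' Welch-Satterthwaite degrees of freedom (via [stats::t.test()]).
#' Degenerate zero-variance cases follow the convention: p = 1 when both
#' samples are constant and equal, p approaches 0 when constant and
#' different.
#'
#' @param errors_a,errors_b Numeric vectors, each of length at least 2.
#' @return p-value in \eqn{[0, 1]}.
#' @export
ttest_pvalue <- function(errors_a, errors_b) {
  stopifnot(length(errors_a) >= 2, length(errors_b) >= 2)
  va <- stats::var(errors_a); vb <- stats::var(errors_b)
  if (va == 0 && vb == 0) {
    return(if (mean(errors_a) == mean(errors_b)) 1.0 else 0.0)
  }
  stats::t.test(errors_a, errors_b, var.equal = FALSE)$p.value
}

# model config with d and seed adjusted for one (fold, k) training run
.model_cfg_for <- function(cfg, d, fold, k) {
  mc <- cfg$model
  mc$d <- as.integer(d)
  mc$seed <- as.integer(cfg$seed + 100000L + 1000L * fold + k)
  mc
}

#' Run the full pipeline
#'
#' For each outer fold, sample selection runs only on that fold's
#' training split, RegGNN is trained on the k selected subjects, and
#' evaluation uses only the untouched test split; this repeats over the k
#' sweep, plus a baseline trained on all training samples and a
#' mean-predictor null.  Fully reproducible given the master seed.
#'
#' @param subjects List of subjects (e.g. from [load_cohort()] or a
#'   [generate_cohort()]'s `$subjects`).
#' @param cfg A [pipeline_config()].
#' @return Object of class `evaluation_report`; see
#'   [write_report()] for the file layout.  Fields: `cells` (per fold and
#'   k: MAE/RMSE), `per_k` (fold means), `summary` (mean/sd/min/max over
#'   k), `baseline`, `mean_predictor`, `best_k`, `ttest_p`, `config`,
#'   `timings`.
#' @export
run_pipeline <- function(subjects, cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (inherits(subjects, "synthetic_cohort")) subjects <- subjects$subjects
  ids <- .check_cohort(subjects, min_n = cfg$outer_folds)
  subjects <- subjects[order(ids)]  # ids, not file order, drive splits
  n <- length(subjects)
  d <- nrow(subjects[[1]]$spd)

  folds <- kfold_split(n, cfg$outer_folds, cfg$seed + 101L)
  max_train <- max(vapply(folds, function(f) length(f$train), integer(1)))
  sel_base <- cfg$selection
  inner_min_train <- min(vapply(folds, function(f) {
    nt <- length(f$train)
    nt - ceiling(nt / sel_base$n_folds)
  }, numeric(1)))
  if (max(cfg$k_sweep) > inner_min_train) {
    stop("k_sweep maximum (", max(cfg$k_sweep),
         ") exceeds the smallest inner train-in size (", inner_min_train,
         ")", call. = FALSE)
  }

  cells <- list()
  abs_errors <- list()  # per k (and baseline): pooled over folds
  t0 <- proc.time()[["elapsed"]]
  timings <- numeric(cfg$outer_folds)

  for (fold in seq_len(cfg$outer_folds)) {
    tf <- proc.time()[["elapsed"]]
    training <- subjects[folds[[fold]]$train]
    test <- subjects[folds[[fold]]$test]
    test_scores <- .subject_scores(test)
    test_graphs <- lapply(test, function(s) {
      preprocess_for_gnn(s$connectome, .model_cfg_for(cfg, d, fold, 0),
                         id = s$id, score = s$score)
    })

    sel_cfg <- sel_base
    sel_cfg$k <- cfg$k_sweep[1]
    sel_cfg$seed <- as.integer(cfg$seed + 211L + fold)
    sel <- select_samples(training, sel_cfg, ks = cfg$k_sweep)

    train_by_id <- stats::setNames(training, .subject_ids(training))
    for (k in cfg$k_sweep) {
      chosen <- train_by_id[sel$selected_by_k[[as.character(k)]]]
      mc <- .model_cfg_for(cfg, d, fold, k)
      graphs <- lapply(chosen, function(s) {
        preprocess_for_gnn(s$connectome, mc, id = s$id, score = s$score)
      })
      fit <- reggnn_train(graphs, mc)
      pred <- reggnn_predict(fit$params, test_graphs, mc)
      key <- as.character(k)
      cells[[length(cells) + 1]] <- data.frame(
        fold = fold, k = key,
        mae = compute_mae(pred, test_scores),
        rmse = compute_rmse(pred, test_scores)
      )
      abs_errors[[key]] <- c(abs_errors[[key]], abs(pred - test_scores))
    }

    # baseline: trained on every training subject
    mc <- .model_cfg_for(cfg, d, fold, 999L)
    graphs_all <- lapply(training, function(s) {
      preprocess_for_gnn(s$connectome, mc, id = s$id, score = s$score)
    })
    fit <- reggnn_train(graphs_all, mc)
    pred <- reggnn_predict(fit$params, test_graphs, mc)
    cells[[length(cells) + 1]] <- data.frame(
      fold = fold, k = "baseline",
      mae = compute_mae(pred, test_scores),
      rmse = compute_rmse(pred, test_scores)
    )
    abs_errors[["baseline"]] <- c(abs_errors[["baseline"]],
                                  abs(pred - test_scores))

    # mean-predictor null: predicts the training-set mean score
    mp <- rep(mean(.subject_scores(training)), length(test))
    cells[[length(cells) + 1]] <- data.frame(
      fold = fold, k = "mean_pred",
      mae = compute_mae(mp, test_scores),
      rmse = compute_rmse(mp, test_scores)
    )
    abs_errors[["mean_pred"]] <- c(abs_errors[["mean_pred"]],
                                   abs(mp - test_scores))
    timings[fold] <- proc.time()[["elapsed"]] - tf
  }

  cells <- do.call(rbind, cells)
  sweep_cells <- cells[!cells$k %in% c("baseline", "mean_pred"), ]
  per_k <- stats::aggregate(cbind(mae, rmse) ~ k, data = sweep_cells, FUN = mean)
  per_k$k_num <- as.integer(per_k$k)
  per_k <- per_k[order(per_k$k_num), c("k_num", "mae", "rmse")]
  names(per_k)[1] <- "k"
  rownames(per_k) <- NULL

  summary_row <- function(v) c(mean = mean(v), sd = stats::sd(v),
                               min = min(v), max = max(v))
  summ <- data.frame(
    metric = c("mae", "rmse"),
    rbind(summary_row(per_k$mae), summary_row(per_k$rmse))
  )
  best_k <- per_k$k[which.min(per_k$mae)]
  baseline <- colMeans(cells[cells$k == "baseline", c("mae", "rmse")])
  mean_pred <- colMeans(cells[cells$k == "mean_pred", c("mae", "rmse")])
  ttest_p <- ttest_pvalue(abs_errors[[as.character(best_k)]],
                          abs_errors[["baseline"]])

  report <- structure(
    list(cells = cells, per_k = per_k, summary = summ,
         baseline = baseline, mean_predictor = mean_pred,
         best_k = best_k, ttest_p = ttest_p,
         config = cfg, n_subjects = n, d = d,
         timings = timings,
         total_time = proc.time()[["elapsed"]] - t0),
    class = "evaluation_report"
  )
  if (!is.null(cfg$output_dir)) write_report(report, cfg$output_dir)
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation over", x$config$outer_folds, "outer folds,",
      x$n_subjects, "subjects, d =", x$d, "\n")
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Human-readable report table
#'
#' @param report An `evaluation_report`.
#' @return Character vector of report lines.
#' @export
format_report <- function(report) {
  pk <- report$per_k
  lines <- c(
    sprintf("%-10s %10s %10s", "k", "MAE", "RMSE"),
    sprintf("%-10d %10.3f %10.3f", pk$k, pk$mae, pk$rmse),
    sprintf("%-10s %10.3f %10.3f", "baseline",
            report$baseline[["mae"]], report$baseline[["rmse"]]),
    sprintf("%-10s %10.3f %10.3f", "mean_pred",
            report$mean_predictor[["mae"]], report$mean_predictor[["rmse"]]),
    sprintf("over k: MAE %.3f +/- %.3f (%.3f, %.3f); RMSE %.3f +/- %.3f (%.3f, %.3f)",
            report$summary$mean[1], report$summary$sd[1],
            report$summary$min[1], report$summary$max[1],
            report$summary$mean[2], report$summary$sd[2],
            report$summary$min[2], report$summary$max[2]),
    sprintf("best k = %d; Welch t-test (best k vs baseline) p = %.4g",
            report$best_k, report$ttest_p)
  )
  lines
}

#' Write the evaluation report to disk
#'
#' Writes `report_cells.csv` (per fold and k), `report_per_k.csv`,
#' `report_summary.csv`, `report.txt` (human-readable), and `run_log.txt`
#' (seed, configuration echo, per-fold timings).  The CSV content is
#' deterministic given the pipeline seed; timings live only in the log.
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "evaluation_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$cells, file.path(dir, "report_cells.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(report$per_k, file.path(dir, "report_per_k.csv"),
                   row.names = FALSE, quote = FALSE)
  summ <- report$summary
  summ$metric <- as.character(summ$metric)
  extra <- data.frame(
    metric = c("baseline_mae", "baseline_rmse", "mean_pred_mae",
               "mean_pred_rmse", "best_k", "ttest_p"),
    mean = c(report$baseline[["mae"]], report$baseline[["rmse"]],
             report$mean_predictor[["mae"]], report$mean_predictor[["rmse"]],
             report$best_k, report$ttest_p),
    sd = NA_real_, min = NA_real_, max = NA_real_
  )
  utils::write.csv(rbind(summ, extra), file.path(dir, "report_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLines(format_report(report), file.path(dir, "report.txt"))
  cfg <- report$config
  writeLines(c(
    paste("seed:", cfg$seed),
    paste("outer_folds:", cfg$outer_folds),
    paste("k_sweep:", paste(cfg$k_sweep, collapse = ",")),
    paste("selection_mode:", cfg$selection$mode),
    paste("selection_n_folds:", cfg$selection$n_folds),
    paste("model_epochs:", cfg$model$epochs),
    paste("model_hidden:", cfg$model$hidden),
    paste("model_dropout:", cfg$model$dropout),
    paste("neg_handling:", cfg$model$neg_handling),
    paste("n_subjects:", report$n_subjects),
    paste("d:", report$d),
    paste("fold_seconds:", paste(sprintf("%.2f", report$timings),
                                 collapse = ",")),
    paste("total_seconds:", sprintf("%.2f", report$total_time))
  ), file.path(dir, "run_log.txt"))
  invisible(dir)
}
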