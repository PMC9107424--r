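#' RegGNN: graph convolutional regression on connectomes
#'
#' @description
#' RegGNN predicts a scalar score from a connectome with two graph
#' convolution layers and a fully connected readout.  The regularized
#' adjacency `P` gets self-loops, `P~ = P + I`, and symmetric degree
#' normalization `A^ = D~^{-1/2} P~ D~^{-1/2}`.  With the activation
#' initialized at the identity, the network computes
#'
#' \deqn{H^{(1)} = ReLU(\hat A W^{(1)}), \quad
#'       H^{(2)} = ReLU(\hat A H^{(1)} W^{(2)}),}
#'
#' with a dropout layer after the first convolution (training only,
#' inverted scaling), and the readout `y^ = w . H^{(2)} + b` maps the
#' resulting d-vector to the predicted score.  Training minimizes mean
#' squared error with Adam; the absolute values of the readout weights
#' rank brain regions by their contribution to the prediction (biomarker
#' discovery).
#'
#' @name reggnn
NULL

#' RegGNN configuration
#'
#' @param d Number of ROIs (the study uses 116).
#' @param hidden Width of the first convolution (default 64).
#' @param dropout Dropout rate after the first convolution (default 0.1).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param weight_decay L2 penalty coefficient (default 0.0005).
#' @param epochs Number of full-batch epochs (default 100).
#' @param seed Integer seed for initialization and dropout.
#' @param mu Regularization constant for [regularize()].
#' @param neg_handling How negative correlations are removed before
#'   training: `"zero_entries"` (default) zeroes negative matrix entries;
#'   `"clamp_eigenvalues"` reconstructs with negative eigenvalues set to
#'   zero.
#' @param bias_init `"mean_score"` (default) initializes the readout bias
#'   at the training-set mean score; `"zero"` starts it at 0.
#' @return Object of class `reggnn_config`.
#' @export
reggnn_config <- function(d = 116L, hidden = 64L, dropout = 0.1,
                          learning_rate = 0.001, weight_decay = 0.0005,
                          epochs = 100L, seed = 1L, mu = 1e-10,
                          neg_handling = c("zero_entries", "clamp_eigenvalues"),
                          bias_init = c("mean_score", "zero")) {
  neg_handling <- match.arg(neg_handling)
  bias_init <- match.arg(bias_init)
  stopifnot(d >= 2, hidden >= 1, dropout >= 0, dropout < 1,
            learning_rate >= 0, weight_decay >= 0, epochs >= 1, mu > 0)
  structure(
    list(d = as.integer(d), hidden = as.integer(hidden), dropout = dropout,
         learning_rate = learning_rate, weight_decay = weight_decay,
         epochs = as.integer(epochs), seed = as.integer(seed), mu = mu,
         neg_handling = neg_handling, bias_init = bias_init),
    class = "reggnn_config"
  )
}

#' Preprocess a connectome for the network
#'
#' Regularizes the correlation matrix, removes negative correlations
#' (training-side only; sample selection keeps them), and computes the
#' symmetrically normalized adjacency with self-loops.
#'
#' @param C Correlation matrix.
#' @param cfg A [reggnn_config()].
#' @param id Optional subject id.
#' @param score Optional score carried along for training.
#' @return Object of class `preprocessed_graph` with `adjacency` (after
#'   negative handling) and `norm_adjacency`.
#' @export
preprocess_for_gnn <- function(C, cfg, id = NULL, score = NA_real_) {
  stopifnot(inherits(cfg, "reggnn_config"))
  P <- regularize(C, mu = cfg$mu, subject = id)
  A <- switch(cfg$neg_handling,
    zero_entries = pmax(P, 0),
    clamp_eigenvalues = {
      e <- eigen(P, symmetric = TRUE)
      M <- .symmetrize(e$vectors %*% (pmax(e$values, 0) * t(e$vectors)))
      M[M < 0 & M > -1e-12] <- 0
      pmax(M, 0)
    }
  )
  At <- A + diag(1, nrow(A))
  dinv <- 1 / sqrt(rowSums(At))
  norm_adj <- .symmetrize(At * tcrossprod(dinv))
  structure(
    list(adjacency = A, norm_adjacency = norm_adj, id = id, score = score),
    class = "preprocessed_graph"
  )
}

#' One graph convolution layer
#'
#' `ReLU(A_norm \%*\% H \%*\% W)`.
#'
#' @param H Activation matrix (d x p).
#' @param norm_adjacency Normalized adjacency (d x d).
#' @param W Weight matrix (p x q).
#' @return d x q activation matrix.
#' @export
gcn_layer <- function(H, norm_adjacency, W) {
  if (ncol(norm_adjacency) != nrow(H) || ncol(H) != nrow(W)) {
    stop("incompatible shapes in gcn_layer", call. = FALSE)
  }
  Z <- norm_adjacency %*% H %*% W
  Z * (Z > 0)
}

#' Initialize RegGNN parameters
#'
#' Seeded uniform Glorot-style initialization,
#' `U(-sqrt(6/(fan_in+fan_out)), +...)` per weight block; the readout bias
#' starts at `mean_score` (or 0, per the configuration).
#'
#' @param cfg A [reggnn_config()].
#' @param mean_score Training-set mean score used when
#'   `cfg$bias_init == "mean_score"`.
#' @return Object of class `reggnn_parameters` with `W1` (d x hidden),
#'   `W2` (hidden x 1), `fc_weights` (length d), `fc_bias`.
#' @export
reggnn_init <- function(cfg, mean_score = 0) {
  stopifnot(inherits(cfg, "reggnn_config"))
  glorot <- function(fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
  }
  withr::with_seed(cfg$seed, {
    structure(
      list(
        W1 = glorot(cfg$d, cfg$hidden),
        W2 = glorot(cfg$hidden, 1L),
        fc_weights = drop(glorot(cfg$d, 1L)),
        fc_bias = if (cfg$bias_init == "mean_score") mean_score else 0
      ),
      class = "reggnn_parameters"
    )
  })
}

# forward pass keeping intermediates for backprop; mask is the (already
# scaled) dropout multiplier or NULL for evaluation
.forward_full <- function(A, params, mask = NULL) {
  Z1 <- A %*% params$W1
  H1 <- Z1 * (Z1 > 0)
  H1d <- if (is.null(mask)) H1 else H1 * mask
  Z2 <- A %*% (H1d %*% params$W2)
  H2 <- Z2 * (Z2 > 0)
  e <- drop(H2)
  list(Z1 = Z1, H1d = H1d, Z2 = Z2, e = e,
       yhat = sum(params$fc_weights * e) + params$fc_bias)
}

#' Forward pass of RegGNN
#'
#' Evaluation mode is deterministic (dropout is inactive); in training
#' mode a dropout mask is drawn from the current RNG with inverted
#' scaling, so evaluation needs no rescaling.
#'
#' @param graph A `preprocessed_graph`.
#' @param params `reggnn_parameters`.
#' @param cfg A [reggnn_config()].
#' @param training Logical; draw and apply dropout?
#' @return Predicted score (scalar).
#' @export
reggnn_forward <- function(graph, params, cfg, training = FALSE) {
  stopifnot(inherits(graph, "preprocessed_graph"),
            inherits(params, "reggnn_parameters"))
  mask <- NULL
  if (training && cfg$dropout > 0) {
    keep <- stats::runif(cfg$d * cfg$hidden) >= cfg$dropout
    mask <- matrix(keep / (1 - cfg$dropout), cfg$d, cfg$hidden)
  }
  .forward_full(graph$norm_adjacency, params, mask)$yhat
}

# loss and gradients of mean squared error over the batch; masks is a
# list parallel to graphs (NULL entries = no dropout)
.reggnn_grads <- function(graphs, params, masks = NULL) {
  n <- length(graphs)
  gW1 <- params$W1 * 0
  gW2 <- params$W2 * 0
  gfc <- params$fc_weights * 0
  gb <- 0
  loss <- 0
  for (i in seq_len(n)) {
    A <- graphs[[i]]$norm_adjacency
    f <- .forward_full(A, params, if (is.null(masks)) NULL else masks[[i]])
    err <- f$yhat - graphs[[i]]$score
    loss <- loss + err^2
    dy <- 2 * err / n
    gb <- gb + dy
    gfc <- gfc + dy * f$e
    dH2 <- matrix(dy * params$fc_weights, ncol = 1)
    dZ2 <- dH2 * (f$Z2 > 0)
    AH1 <- A %*% f$H1d
    gW2 <- gW2 + crossprod(AH1, dZ2)
    dH1d <- (A %*% dZ2) %*% t(params$W2)
    dH1 <- if (is.null(masks) || is.null(masks[[i]])) dH1d else
      dH1d * masks[[i]]
    dZ1 <- dH1 * (f$Z1 > 0)
    gW1 <- gW1 + crossprod(A, dZ1)
  }
  list(loss = loss / n,
       W1 = gW1, W2 = gW2, fc_weights = gfc, fc_bias = gb)
}

#' Train RegGNN
#'
#' Full-batch gradient descent on mean squared error with the Adam
#' optimizer (beta1 = 0.9, beta2 = 0.999, eps = 1e-8) and classical L2
#' weight decay added to the gradients of `W1`, `W2` and the readout
#' weights (not the bias).  Training is bit-reproducible for a fixed seed
#' on one platform.
#'
#' @param graphs List of `preprocessed_graph` objects with scores.
#' @param cfg A [reggnn_config()].
#' @return List with `params` (trained `reggnn_parameters`) and
#'   `loss_history` (MSE per epoch, length `cfg$epochs`).
#' @export
reggnn_train <- function(graphs, cfg) {
  stopifnot(inherits(cfg, "reggnn_config"))
  if (length(graphs) < 1) stop("need at least one training sample", call. = FALSE)
  if (any(!is.finite(vapply(graphs, `[[`, numeric(1), "score")))) {
    stop("all training graphs need a finite score", call. = FALSE)
  }
  mean_score <- mean(vapply(graphs, `[[`, numeric(1), "score"))
  params <- reggnn_init(cfg, mean_score)

  decayed <- c("W1", "W2", "fc_weights")
  blocks <- c(decayed, "fc_bias")
  m <- lapply(params[blocks], function(p) p * 0)
  v <- m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  loss_history <- numeric(cfg$epochs)

  withr::with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$epochs)) {
      masks <- NULL
      if (cfg$dropout > 0) {
        masks <- lapply(graphs, function(g) {
          keep <- stats::runif(cfg$d * cfg$hidden) >= cfg$dropout
          matrix(keep / (1 - cfg$dropout), cfg$d, cfg$hidden)
        })
      }
      g <- .reggnn_grads(graphs, params, masks)
      if (!is.finite(g$loss)) {
        stop("training diverged (non-finite loss at epoch ", epoch, ")",
             call. = FALSE)
      }
      loss_history[epoch] <- g$loss
      for (nm in blocks) {
        grad <- g[[nm]]
        if (nm %in% decayed) grad <- grad + cfg$weight_decay * params[[nm]]
        m[[nm]] <- b1 * m[[nm]] + (1 - b1) * grad
        v[[nm]] <- b2 * v[[nm]] + (1 - b2) * grad^2
        mhat <- m[[nm]] / (1 - b1^epoch)
        vhat <- v[[nm]] / (1 - b2^epoch)
        params[[nm]] <- params[[nm]] -
          cfg$learning_rate * mhat / (sqrt(vhat) + eps)
      }
    }
  })
  list(params = params, loss_history = loss_history)
}

#' Predict scores for a list of graphs
#'
#' Evaluation-mode forward pass per graph, order preserved.
#'
#' @param params Trained `reggnn_parameters`.
#' @param graphs List of `preprocessed_graph`.
#' @param cfg A [reggnn_config()].
#' @return Numeric vector of predicted scores.
#' @export
reggnn_predict <- function(params, graphs, cfg) {
  vapply(graphs, reggnn_forward, numeric(1),
         params = params, cfg = cfg, training = FALSE)
}

#' Rank brain regions by readout weight magnitude
#'
#' The final fully connected layer maps one feature per ROI to the
#' predicted score; the absolute value of each weight quantifies that
#' region's contribution and serves as a biomarker ranking.
#'
#' @param params `reggnn_parameters`.
#' @return `data.frame` with columns `roi` (1-based index), `weight`,
#'   `abs_weight`, `rank`, sorted by descending `abs_weight` (ties by
#'   ascending index).
#' @export
region_weights <- function(params) {
  stopifnot(inherits(params, "reggnn_parameters"))
  w <- params$fc_weights
  ord <- order(-abs(w), seq_along(w))
  data.frame(
    roi = ord,
    weight = w[ord],
    abs_weight = abs(w[ord]),
    rank = seq_along(w)
  )
}

#' Average region rankings across several trained models
#'
#' Used to aggregate biomarker rankings over models trained for each k in
#' the sweep: each model contributes the rank position of every ROI, and
#' regions are re-ranked by mean rank (ties by ascending index).
#'
#' @param params_list List of `reggnn_parameters`.
#' @return `data.frame` with `roi`, `mean_rank`, `rank`.
#' @export
average_region_rankings <- function(params_list) {
  stopifnot(length(params_list) >= 1)
  ranks <- vapply(params_list, function(p) {
    rw <- region_weights(p)
    rw$rank[order(rw$roi)]
  }, numeric(length(params_list[[1]]$fc_weights)))
  mean_rank <- rowMeans(as.matrix(ranks))
  ord <- order(mean_rank, seq_along(mean_rank))
  data.frame(roi = ord, mean_rank = mean_rank[ord],
             rank = seq_along(mean_rank))
}

#' Serialize / restore RegGNN parameters
#'
#' Plain-text portable format: a header line per block giving its name
#' and shape, followed by the values in full precision, row-major.
#'
#' @param params `reggnn_parameters`.
#' @param path File path.
#' @return `write_reggnn_params` returns `path` invisibly;
#'   `read_reggnn_params` returns the parameters.
#' @export
write_reggnn_params <- function(params, path) {
  stopifnot(inherits(params, "reggnn_parameters"))
  con <- file(path, "w")
  on.exit(close(con))
  emit <- function(name, x) {
    x <- as.matrix(x)
    writeLines(paste("#", name, nrow(x), ncol(x)), con)
    writeLines(apply(x, 1, function(r) paste(sprintf("%.17g", r),
                                             collapse = " ")), con)
  }
  emit("W1", params$W1)
  emit("W2", params$W2)
  emit("fc_weights", matrix(params$fc_weights, nrow = 1))
  emit("fc_bias", matrix(params$fc_bias, 1, 1))
  invisible(path)
}

#' @rdname write_reggnn_params
#' @export
read_reggnn_params <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    hdr <- strsplit(lines[i], " ")[[1]]
    stopifnot(hdr[1] == "#")
    nr <- as.integer(hdr[3]); nc <- as.integer(hdr[4])
    vals <- do.call(rbind, lapply(lines[i + seq_len(nr)], function(l) {
      as.numeric(strsplit(l, " ")[[1]])
    }))
    out[[hdr[2]]] <- matrix(vals, nr, nc)
    i <- i + nr + 1
  }
  structure(
    list(W1 = out$W1, W2 = out$W2,
         fc_weights = drop(out$fc_weights), fc_bias = drop(out$fc_bias)),
    class = "reggnn_parameters"
  )
}

#' Write the region-weight biomarker table
#'
#' @param params `reggnn_parameters` (or a list of them, which is
#'   averaged with [average_region_rankings()]).
#' @param path Output file (tab-separated).
#' @return The table, invisibly.
#' @export
write_region_weights <- function(params, path) {
  df <- if (inherits(params, "reggnn_parameters")) region_weights(params)
        else average_region_rankings(params)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
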