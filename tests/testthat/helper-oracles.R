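# Independent brute-force oracles used to cross-check the implementation.
# Everything here is deliberately written from first principles with base R
# (dense eigendecompositions, Floyd-Warshall, normal equations via
# pseudoinverse) and shares no code with the package internals.

# random SPD matrix via a Gram matrix with a positive ridge
rand_spd <- function(d, scale = 1) {
  M <- matrix(stats::rnorm(d * d, sd = scale), d, d)
  crossprod(M) / d + diag(0.5, d)
}

# random symmetric weight matrix with signed entries and a given edge
# probability (zeros = absent edges)
rand_weights <- function(d, p_edge = 0.7) {
  W <- matrix(0, d, d)
  m <- d * (d - 1) / 2
  vals <- stats::rnorm(m) * (stats::runif(m) < p_edge)
  W[upper.tri(W)] <- vals
  W + t(W)
}

# random orthogonal matrix (QR with sign fix)
rand_orthogonal <- function(d) {
  qr_ <- qr(matrix(stats::rnorm(d * d), d, d))
  Q <- qr.Q(qr_)
  Q %*% diag(sign(diag(qr.R(qr_))), d)
}

oracle_degree <- function(W) {
  d <- nrow(W)
  out <- numeric(d)
  for (i in seq_len(d)) {
    for (j in seq_len(d)) if (j != i) out[i] <- out[i] + abs(W[i, j])
  }
  out / (d - 1)
}

oracle_eigenvector <- function(W) {
  A <- abs(W); diag(A) <- 0
  v <- eigen(A, symmetric = TRUE)$vectors[, 1]
  v <- abs(v)
  v / sqrt(sum(v^2))
}

# all-pairs shortest paths by Floyd-Warshall on lengths 1/|w|
oracle_closeness <- function(W) {
  A <- abs(W); diag(A) <- 0
  d <- nrow(A)
  D <- matrix(Inf, d, d); diag(D) <- 0
  D[A > 0] <- 1 / A[A > 0]
  for (k in seq_len(d)) {
    for (i in seq_len(d)) {
      for (j in seq_len(d)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  vapply(seq_len(d), function(i) {
    reach <- which(is.finite(D[i, ]) & seq_len(d) != i)
    r <- length(reach)
    if (r == 0) return(0)
    (r / (d - 1)) * (r / sum(D[i, reach]))
  }, numeric(1))
}

oracle_logm <- function(P) {
  e <- eigen((P + t(P)) / 2, symmetric = TRUE)
  e$vectors %*% diag(log(e$values), nrow(P)) %*% t(e$vectors)
}

oracle_minmax <- function(v) {
  if (max(v) == min(v)) return(rep(0, length(v)))
  (v - min(v)) / (max(v) - min(v))
}

oracle_pair_features <- function(Pi, Pj, mode, Li, Lj) {
  S <- Lj - Li
  S <- (S + t(S)) / 2
  switch(mode,
    tm = S[lower.tri(S, diag = TRUE)],
    dc = oracle_degree(S),
    ec = oracle_eigenvector(S),
    cc = oracle_closeness(S),
    cnu = c(oracle_degree(S), oracle_eigenvector(S), oracle_closeness(S)),
    cns = c(oracle_minmax(oracle_degree(S)),
            oracle_minmax(oracle_eigenvector(S)),
            oracle_minmax(oracle_closeness(S))),
    g = sqrt(sum(S^2)),
    a = {
      ui <- Pi[lower.tri(Pi, diag = TRUE)]
      uj <- Pj[lower.tri(Pj, diag = TRUE)]
      sqrt(sum((ui - uj)^2))
    }
  )
}

# least squares with intercept via the Moore-Penrose pseudoinverse
oracle_lstsq <- function(X, y) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  coef <- drop(MASS::ginv(Xc) %*% (y - ym))
  list(coef = coef, intercept = ym - sum(coef * xm))
}

# straightforward independent re-implementation of the whole selection
# procedure (same seed/shuffle convention, no shared code paths)
oracle_select <- function(subjects, k, n_folds, mode, seed) {
  n <- length(subjects)
  ids <- vapply(subjects, function(s) s$id, character(1))
  scores <- vapply(subjects, function(s) s$score, numeric(1))
  logs <- lapply(subjects, function(s) oracle_logm(s$spd))
  feat <- function(i, j) {
    oracle_pair_features(subjects[[i]]$spd, subjects[[j]]$spd, mode,
                         logs[[i]], logs[[j]])
  }
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  base <- n %/% n_folds; extra <- n %% n_folds
  fold_of <- rep(seq_len(n_folds), times = base + (seq_len(n_folds) <= extra))
  counts <- stats::setNames(integer(n), sort(ids))
  for (f in seq_len(n_folds)) {
    ho <- perm[fold_of == f]
    tr <- perm[fold_of != f]
    rows <- list(); ys <- numeric(0)
    for (a in seq_along(tr)) {
      for (b in seq_along(tr)) {
        if (a < b) {
          rows[[length(rows) + 1]] <- feat(tr[a], tr[b])
          ys <- c(ys, abs(scores[tr[b]] - scores[tr[a]]))
        }
      }
    }
    X <- do.call(rbind, rows)
    fit <- oracle_lstsq(X, ys)
    for (l in ho) {
      pr <- vapply(tr, function(s) {
        sum(fit$coef * feat(s, l)) + fit$intercept
      }, numeric(1))
      top <- tr[order(pr, ids[tr])[seq_len(k)]]
      counts[ids[top]] <- counts[ids[top]] + 1L
    }
  }
  ord <- order(-counts, names(counts))
  list(counts = counts,
       selected = sort(names(counts)[ord[seq_len(k)]]))
}

# compact cohort helper for tests
tiny_cohort <- function(n, d, seed, coupling = "cluster_only",
                        n_clusters = 3, ...) {
  generate_cohort(cohort_spec(n_subjects = n, d = d,
                              n_clusters = n_clusters,
                              coupling = coupling, seed = seed, ...))
}
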