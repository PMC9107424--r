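test_that("preprocessing zeroes negative correlations and normalizes with self-loops", {
  cfg <- reggnn_config(d = 2, mu = 1e-10)
  C <- matrix(c(1, -0.5, -0.5, 1), 2, 2)
  g <- preprocess_for_gnn(C, cfg)
  expect_equal(g$adjacency, diag(1 + 1e-10, 2), tolerance = 1e-9)

  # C = I: A + I = 2I, D = 2I, normalized adjacency = I
  g2 <- preprocess_for_gnn(diag(2), cfg)
  expect_equal(g2$norm_adjacency, diag(2), tolerance = 1e-9)

  # clamped eigenvalue variant also yields a non-negative adjacency
  cfg_c <- reggnn_config(d = 3, neg_handling = "clamp_eigenvalues")
  set.seed(1)
  C3 <- make_random_correlation(3)
  g3 <- preprocess_for_gnn(C3, cfg_c)
  expect_true(all(g3$adjacency >= 0))
})

test_that("the normalized adjacency is symmetric with spectral radius at most one", {
  set.seed(2)
  cfg <- reggnn_config(d = 10)
  for (rep in 1:10) {
    C <- make_random_correlation(10)
    g <- preprocess_for_gnn(C, cfg)
    expect_lt(max(abs(g$norm_adjacency - t(g$norm_adjacency))), 1e-12)
    rho <- max(abs(eigen(g$norm_adjacency, symmetric = TRUE,
                         only.values = TRUE)$values))
    expect_lte(rho, 1 + 1e-8)
  }
})

test_that("gcn_layer applies normalization, weights and ReLU", {
  A <- matrix(0.5, 2, 2)
  expect_equal(gcn_layer(diag(2), A, matrix(1, 2, 1)), matrix(1, 2, 1))
  expect_equal(gcn_layer(diag(2), A, matrix(0, 2, 3)), matrix(0, 2, 3))
  expect_equal(gcn_layer(diag(2), A, matrix(-1, 2, 1)), matrix(0, 2, 1))
  expect_error(gcn_layer(diag(3), A, matrix(1, 2, 1)), "incompatible")
})

test_that("the d = 2 worked example evaluates to exactly 2", {
  cfg <- reggnn_config(d = 2, hidden = 2, dropout = 0)
  A <- matrix(0.5, 2, 2)
  g <- structure(list(adjacency = A, norm_adjacency = A, id = "w",
                      score = NA_real_), class = "preprocessed_graph")
  p <- structure(list(W1 = diag(2), W2 = matrix(1, 2, 1),
                      fc_weights = c(1, 1), fc_bias = 0),
                 class = "reggnn_parameters")
  expect_identical(reggnn_forward(g, p, cfg), 2)

  # zero parameters: output is the bias
  p0 <- structure(list(W1 = matrix(0, 2, 2), W2 = matrix(0, 2, 1),
                       fc_weights = c(0, 0), fc_bias = 42),
                  class = "reggnn_parameters")
  expect_identical(reggnn_forward(g, p0, cfg), 42)

  # evaluation mode is deterministic
  expect_identical(reggnn_forward(g, p, cfg), reggnn_forward(g, p, cfg))
})

test_that("analytic gradients match finite differences", {
  cfg <- reggnn_config(d = 4, hidden = 3, dropout = 0, seed = 2)
  co <- tiny_cohort(3, 4, seed = 5, n_clusters = 1,
                    score_centers = 100)
  graphs <- lapply(co$subjects, function(s) {
    preprocess_for_gnn(s$connectome, cfg, s$id, s$score)
  })
  params <- reggnn_init(cfg, 100)
  gr <- reggnn:::.reggnn_grads(graphs, params)
  eps <- 1e-6
  for (blk in c("W1", "W2", "fc_weights", "fc_bias")) {
    v <- params[[blk]]
    num <- v
    for (i in seq_along(v)) {
      pp <- params; pp[[blk]][i] <- v[i] + eps
      lp <- reggnn:::.reggnn_grads(graphs, pp)$loss
      pm <- params; pm[[blk]][i] <- v[i] - eps
      lm <- reggnn:::.reggnn_grads(graphs, pm)$loss
      num[i] <- (lp - lm) / (2 * eps)
    }
    rel <- max(abs(num - gr[[blk]])) / max(abs(num) + 1e-10)
    expect_lt(rel, 1e-4)
  }
})

test_that("the graph stack is equivariant under node permutations", {
  set.seed(3)
  cfg <- reggnn_config(d = 5, hidden = 4, dropout = 0)
  C <- make_random_correlation(5)
  g <- preprocess_for_gnn(C, cfg)
  params <- reggnn_init(cfg, 0)
  y <- reggnn_forward(g, params, cfg)

  perm <- sample(5)
  Pm <- diag(5)[perm, ]
  g_p <- g
  g_p$norm_adjacency <- Pm %*% g$norm_adjacency %*% t(Pm)
  params_p <- params
  params_p$W1 <- Pm %*% params$W1
  params_p$fc_weights <- drop(Pm %*% params$fc_weights)
  expect_equal(reggnn_forward(g_p, params_p, cfg), y, tolerance = 1e-12)
})

test_that("training is reproducible, records losses, and freezes at zero learning rate", {
  co <- tiny_cohort(4, 6, seed = 9)
  cfg <- reggnn_config(d = 6, hidden = 8, epochs = 20, seed = 31)
  graphs <- lapply(co$subjects, function(s) {
    preprocess_for_gnn(s$connectome, cfg, s$id, s$score)
  })
  fit1 <- reggnn_train(graphs, cfg)
  fit2 <- reggnn_train(graphs, cfg)
  expect_length(fit1$loss_history, 20)
  expect_identical(fit1$params, fit2$params)
  expect_identical(fit1$loss_history, fit2$loss_history)

  cfg0 <- reggnn_config(d = 6, hidden = 8, epochs = 5, seed = 31,
                        learning_rate = 0)
  fit0 <- reggnn_train(graphs, cfg0)
  init <- reggnn_init(cfg0, mean(vapply(graphs, `[[`, numeric(1), "score")))
  expect_identical(fit0$params, init)

  expect_error(reggnn_train(list(), cfg), "at least one")
})

test_that("training loss decreases in 50-epoch windows when overfitting few samples", {
  co <- tiny_cohort(4, 10, seed = 12)
  cfg <- reggnn_config(d = 10, epochs = 200, seed = 1)
  graphs <- lapply(co$subjects, function(s) {
    preprocess_for_gnn(s$connectome, cfg, s$id, s$score)
  })
  fit <- reggnn_train(graphs, cfg)
  win <- vapply(split(fit$loss_history, rep(1:4, each = 50)), mean,
                numeric(1))
  expect_true(all(diff(win) < 0))
})

test_that("region weights rank ROIs by readout magnitude with stable ties", {
  p <- structure(list(W1 = NULL, W2 = NULL,
                      fc_weights = c(0.1, -0.9, 0.5), fc_bias = 0),
                 class = "reggnn_parameters")
  rw <- region_weights(p)
  expect_equal(rw$roi, c(2, 3, 1))
  expect_equal(rw$weight, c(-0.9, 0.5, 0.1))

  p_tie <- p; p_tie$fc_weights <- c(0.5, 0.5, 0.5)
  expect_equal(region_weights(p_tie)$roi, 1:3)

  avg <- average_region_rankings(list(p, p))
  expect_equal(avg$roi, rw$roi)
  expect_equal(avg$mean_rank, as.numeric(1:3))
})

test_that("parameters survive a text round-trip and predictions match", {
  co <- tiny_cohort(3, 5, seed = 2)
  cfg <- reggnn_config(d = 5, hidden = 4, epochs = 10, seed = 3)
  graphs <- lapply(co$subjects, function(s) {
    preprocess_for_gnn(s$connectome, cfg, s$id, s$score)
  })
  fit <- reggnn_train(graphs, cfg)
  path <- withr::local_tempfile(fileext = ".txt")
  write_reggnn_params(fit$params, path)
  back <- read_reggnn_params(path)
  expect_equal(back$W1, fit$params$W1)
  expect_equal(back$fc_weights, fit$params$fc_weights)
  expect_equal(reggnn_predict(back, graphs, cfg),
               reggnn_predict(fit$params, graphs, cfg))
  # predict is a plain map over forward
  expect_identical(reggnn_predict(fit$params, graphs[1], cfg),
                   reggnn_forward(graphs[[1]], fit$params, cfg))
})
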