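test_that("random correlation matrices satisfy every connectome invariant", {
  set.seed(1)
  for (d in c(2, 5, 12)) {
    for (rep in 1:10) {
      C <- make_random_correlation(d)
      expect_silent(check_correlation(C))
      expect_equal(max(abs(diag(C) - 1)), 0, tolerance = 1e-10)
      expect_gt(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values),
                0)
      expect_true(all(abs(C) <= 1 + 1e-9))
    }
  }
})

test_that("zero-noise cohorts collapse each cluster to one point", {
  co <- generate_cohort(cohort_spec(n_subjects = 9, d = 8, n_clusters = 3,
                                    within_cluster_sd = 0, score_sd = 0,
                                    score_centers = c(90, 110, 130),
                                    seed = 3))
  cl <- vapply(co$ground_truth, `[[`, numeric(1), "cluster")
  for (c in 1:3) {
    members <- co$subjects[cl == c]
    expect_equal(members[[1]]$connectome, members[[2]]$connectome)
    scores <- vapply(members, `[[`, numeric(1), "score")
    expect_true(all(scores == scores[1]))
  }
})

test_that("cohort generation is deterministic given the seed", {
  spec <- cohort_spec(n_subjects = 8, d = 6, seed = 11)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(lapply(a$subjects, `[[`, "connectome"),
                   lapply(b$subjects, `[[`, "connectome"))
  expect_identical(vapply(a$subjects, `[[`, numeric(1), "score"),
                   vapply(b$subjects, `[[`, numeric(1), "score"))
})

test_that("generated score statistics match the cohort specification", {
  # single cluster emulating a neurotypical FIQ distribution
  mu_target <- 111.573; sd_target <- 12.056
  scores <- unlist(lapply(0:9, function(seed) {
    co <- generate_cohort(cohort_spec(n_subjects = 30, d = 5,
                                      n_clusters = 1,
                                      score_centers = mu_target,
                                      score_sd = sd_target, seed = seed))
    vapply(co$subjects, `[[`, numeric(1), "score")
  }))
  n <- length(scores)
  expect_lt(abs(mean(scores) - mu_target), 3 * sd_target / sqrt(n))
  # sd of the sample sd is approximately sd / sqrt(2 n)
  expect_lt(abs(sd(scores) - sd_target), 3 * sd_target / sqrt(2 * n))
})

test_that("shrinking within-cluster spread separates clusters geometrically", {
  co <- generate_cohort(cohort_spec(n_subjects = 12, d = 8, n_clusters = 3,
                                    within_cluster_sd = 0.01, seed = 7))
  cl <- vapply(co$ground_truth, `[[`, numeric(1), "cluster")
  within <- c(); between <- c()
  for (i in 1:11) {
    for (j in (i + 1):12) {
      dd <- log_euclidean_distance(co$subjects[[i]]$spd,
                                   co$subjects[[j]]$spd)
      if (cl[i] == cl[j]) within <- c(within, dd) else between <- c(between, dd)
    }
  }
  expect_lt(max(within), 0.2)
  expect_gt(min(between), 1)
})

test_that("the linear tangent coupling is learnable to near-perfect R^2", {
  co <- generate_cohort(cohort_spec(n_subjects = 15, d = 10, n_clusters = 3,
                                    score_centers = c(80, 120, 160),
                                    coupling = "linear_in_tangent",
                                    score_sd = 0, coupling_score_sd = 2,
                                    seed = 5))
  pairs <- reggnn:::.train_in_pairs(co$subjects, "dc")
  f <- fit_difference_regressor(pairs$X, pairs$y)
  resid <- pairs$y - predict(f, pairs$X)
  r2 <- 1 - sum(resid^2) / sum((pairs$y - mean(pairs$y))^2)
  expect_gt(r2, 0.99)
})

test_that("written cohorts round-trip through load_cohort", {
  co <- generate_cohort(cohort_spec(n_subjects = 5, d = 6, seed = 21))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- load_cohort(dir, file.path(dir, "scores.csv"))
  expect_equal(length(back), 5)
  for (i in 1:5) {
    expect_identical(back[[i]]$id, co$subjects[[i]]$id)
    expect_lt(max(abs(back[[i]]$connectome - co$subjects[[i]]$connectome)),
              1e-12)
    expect_equal(back[[i]]$score, co$subjects[[i]]$score)
  }
})
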