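test_that("degenerate partitions behave as forced: k = m and k = 1", {
  set.seed(7)
  x <- matrix(rnorm(24), nrow = 8)
  rownames(x) <- paste0("s", 1:8)

  fit <- kmeans_fit(x, k = nrow(x), restarts = 5, seed = 1)
  expect_equal(fit$objective, 0, tolerance = 1e-12)
  expect_identical(sort(unique(fit$labels)), 1:8)

  fit1 <- kmeans_fit(x, k = 1, restarts = 1, seed = 1)
  expect_equal(unname(fit1$centroids[1, ]), unname(colMeans(x)),
               tolerance = 1e-12)
  expect_equal(fit1$objective, sum(sweep(x, 2, colMeans(x))^2),
               tolerance = 1e-9)
})

test_that("invalid k and mismatched dimensions error", {
  x <- matrix(rnorm(10), nrow = 5)
  expect_error(kmeans_single(x, k = 0), ">= 1")
  expect_error(kmeans_single(x, k = 6), "exceeds")
  fit <- kmeans_fit(x, k = 2, restarts = 2, seed = 1)
  expect_error(objective(x[1:3, ], fit), "do not cover")
  expect_error(objective(x[, 1, drop = FALSE], fit), "dimensions")
})

test_that("fitted models satisfy the centroid-mean and argmin invariants", {
  set.seed(13)
  for (trial in 1:5) {
    x <- matrix(rnorm(15 * 4), nrow = 15)
    k <- sample(2:4, 1)
    fit <- kmeans_fit(x, k = k, restarts = 10, seed = trial)
    expect_identical(sort(unique(fit$labels)), seq_len(k))
    for (j in seq_len(k)) {
      expect_equal(unname(fit$centroids[j, ]),
                   unname(colMeans(x[fit$labels == j, , drop = FALSE])),
                   tolerance = 1e-9)
    }
    d2 <- t(apply(x, 1, function(p)
      colSums((t(fit$centroids) - p)^2)))
    expect_identical(max.col(-d2, ties.method = "first"), fit$labels)
    expect_equal(objective(x, fit), fit$objective, tolerance = 1e-9)
  }
})

test_that("objective matches the tiny hand example", {
  x <- matrix(c(0, 2), ncol = 1)
  fit <- kmeans_fit(x, k = 1, restarts = 1, seed = 1)
  expect_equal(unname(fit$centroids[1, 1]), 1)
  expect_equal(fit$objective, 2)
})

test_that("restarts: determinism, min property, single-restart equality", {
  set.seed(19)
  x <- matrix(rnorm(60), nrow = 12)
  a <- kmeans_fit(x, k = 3, restarts = 20, seed = 99)
  b <- kmeans_fit(x, k = 3, restarts = 20, seed = 99)
  expect_identical(a$labels, b$labels)
  expect_identical(a$centroids, b$centroids)
  expect_true(all(a$objective <= a$restart_objectives + 1e-12))

  one <- kmeans_fit(x, k = 3, restarts = 1, seed = 5)
  set.seed(5)
  seed1 <- sample.int(.Machine$integer.max, 1)
  expect_equal(one$objective,
               kmeans_single(x, 3, seed = seed1)$objective,
               tolerance = 1e-12)
})

test_that("objective traces are monotone within every restart", {
  set.seed(29)
  x <- matrix(rnorm(40 * 6), nrow = 40)
  fit <- kmeans_fit(x, k = 4, restarts = 25, seed = 3)
  for (trace in fit$restart_traces) {
    expect_true(all(diff(trace) <= 1e-9))
  }
})

test_that("multi-restart fit attains the exhaustive-enumeration optimum", {
  set.seed(43)
  for (trial in 1:4) {
    m <- sample(6:10, 1)
    k <- sample(2:3, 1)
    x <- matrix(rnorm(m * 3), nrow = m)
    fit <- kmeans_fit(x, k = k, restarts = 200, seed = trial)
    expect_equal(fit$objective, oracle_best_objective(x, k),
                 tolerance = 1e-9)
  }
})

test_that("two planted families are recovered exactly with k = 2", {
  d <- generate_dataset(list(
    family_spec("p2", 6, 60, 0.02, motif = "AT"),
    family_spec("p3", 6, 60, 0.02, motif = "ACA")), seed = 8)
  ss <- spectrum_set(d$sequences)
  fit <- kmeans_fit(ss, k = 2, restarts = 200, seed = 8)
  truth <- group_labels(d$groups, ss$ids)
  expect_equal(adjusted_rand_index(fit$labels, truth), 1)
  expect_equal(fit$objective, oracle_best_objective(ss$spectra, 2),
               tolerance = 1e-9)
})

test_that("permuting input rows leaves the best objective unchanged", {
  set.seed(53)
  x <- matrix(rnorm(30 * 5), nrow = 30)
  perm <- sample(nrow(x))
  a <- kmeans_fit(x, k = 3, restarts = 50, seed = 4)
  b <- kmeans_fit(x[perm, ], k = 3, restarts = 50, seed = 4)
  expect_equal(a$objective, b$objective, tolerance = 1e-7)
})

test_that("relabel_by_distance renumbers clusters without changing the fit", {
  set.seed(59)
  x <- matrix(rnorm(20 * 4), nrow = 20)
  fit <- kmeans_fit(x, k = 4, restarts = 20, seed = 2)
  rel <- relabel_by_distance(fit)
  expect_equal(rel$objective, objective(x, rel), tolerance = 1e-9)
  expect_equal(adjusted_rand_index(fit$labels, rel$labels), 1)
  M <- main_centroid(rel)
  d <- sqrt(colSums((t(rel$centroids) - M)^2))
  expect_true(all(diff(d) >= -1e-12))
})

test_that("adjusted_rand_index matches known values", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 1, 2)), 0)
  expect_equal(adjusted_rand_index(c(1, 1, 1, 2, 2, 2),
                                   c(1, 1, 2, 2, 2, 2)),
               0.3243243, tolerance = 1e-6)
  set.seed(61)
  a <- sample(1:3, 300, replace = TRUE)
  b <- sample(1:3, 300, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.1)
})
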