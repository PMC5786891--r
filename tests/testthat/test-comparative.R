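make_groups <- function(ids, labels) {
  group_table(data.frame(id = ids, family = labels,
                         stringsAsFactors = FALSE))
}

test_that("decomposition counts distinct clusters per group", {
  ids <- paste0("s", 1:9)
  groups <- make_groups(ids, rep(c("g1", "g2", "g3"), each = 3))
  asg <- list(
    "2" = setNames(c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L), ids),
    "4" = setNames(c(1L, 2L, 2L, 3L, 3L, 3L, 4L, 1L, 2L), ids))
  res <- decomposition(asg, groups)
  wide <- attr(res, "wide")
  expect_identical(unname(wide["g1", "2"]), 1L)
  expect_identical(unname(wide["g2", "2"]), 2L)
  expect_identical(unname(wide["g1", "4"]), 2L)
  expect_identical(unname(wide["g3", "4"]), 3L)
  # counts bounded by min(k, group size), >= 1
  expect_true(all(res$n_clusters >= 1))
  expect_true(all(res$n_clusters <= pmin(res$k, 3)))
})

test_that("decomposition is invariant to cluster relabeling", {
  set.seed(83)
  ids <- paste0("s", 1:12)
  groups <- make_groups(ids, rep(c("a", "b"), each = 6))
  labels <- setNames(sample(1:4, 12, replace = TRUE), ids)
  perm <- sample(4)
  relabeled <- setNames(perm[labels], ids)
  r1 <- decomposition(list("4" = labels), groups)
  r2 <- decomposition(list("4" = relabeled), groups)
  expect_identical(r1$n_clusters, r2$n_clusters)
})

test_that("decomposition validates id coverage", {
  groups <- make_groups(c("s1", "s2"), c("a", "b"))
  expect_error(decomposition(list("1" = setNames(1L, "s3")), groups),
               "do not match")
  expect_error(decomposition(list(), groups), "no assignments")
})

test_that("reference_centroids averages spectra per true group", {
  x <- matrix(c(0, 2, 10, 10), ncol = 1,
              dimnames = list(paste0("s", 1:4), NULL))
  groups <- make_groups(paste0("s", 1:4), c("g1", "g1", "g2", "g2"))
  refs <- reference_centroids(x, groups)
  expect_equal(unname(refs["g1", 1]), 1)
  expect_equal(unname(refs["g2", 1]), 10)

  # singleton group: centroid equals its spectrum
  g2 <- make_groups(paste0("s", 1:4), c("g1", "g1", "g1", "solo"))
  refs2 <- reference_centroids(x, g2)
  expect_equal(unname(refs2["solo", 1]), 10)
})

test_that("msd_matrix reproduces trivial and planted patterns", {
  # members identical to the centroid: own column is exactly 0
  x <- rbind(c(1, 1), c(1, 1), c(4, 0))
  rownames(x) <- paste0("s", 1:3)
  fit <- kmeans_fit(x, k = 2, restarts = 10, seed = 1)
  groups <- make_groups(rownames(x), c("a", "a", "b"))
  refs <- reference_centroids(x, groups)
  cmp <- msd_matrix(x, fit, refs)
  expect_true(all(cmp$msd >= 0))
  expect_equal(min(cmp$msd[, "own"]), 0, tolerance = 1e-12)
  # perfect clustering: own column equals the matching reference column
  for (j in 1:2) {
    expect_equal(cmp$msd[j, "own"], min(cmp$msd[j, -1]),
                 tolerance = 1e-12)
  }
  expect_error(msd_matrix(x, fit, refs[, 1, drop = FALSE]),
               "differ in dimension")
})

test_that("planted two-family data shows the own-family separability", {
  d <- generate_dataset(list(
    family_spec("fam1", 8, 90, 0.02, motif = "AT"),
    family_spec("fam2", 8, 90, 0.02, motif = "ACA")), seed = 77)
  ss <- spectrum_set(d$sequences)
  fit <- kmeans_fit(ss, k = 2, restarts = 50, seed = 77)
  refs <- reference_centroids(ss, d$groups)
  cmp <- msd_matrix(ss, fit, refs)
  truth <- group_labels(d$groups, ss$ids)
  for (j in 1:2) {
    own_family <- unique(truth[fit$labels == j])
    expect_length(own_family, 1)  # clustering is exact by construction
    other <- setdiff(rownames(refs), own_family)
    expect_lt(cmp$msd[j, own_family], min(cmp$msd[j, other]))
  }
  # centroid-to-centroid export agrees with the same structure
  for (j in 1:2) {
    own_family <- unique(truth[fit$labels == j])
    expect_equal(unname(which.min(cmp$centroid_distances[j, ])),
                 match(own_family, colnames(cmp$centroid_distances)))
  }
})

test_that("k = m forced partition gives per-group counts = group sizes", {
  d <- generate_dataset(list(
    family_spec("a", 3, 30, 0.05, motif = "AT"),
    family_spec("b", 4, 30, 0.05)), seed = 5)
  ss <- spectrum_set(d$sequences)
  m <- length(ss$ids)
  fit <- kmeans_fit(ss, k = m, restarts = 3, seed = 5)
  res <- decomposition(list("7" = setNames(fit$labels, ss$ids)), d$groups)
  wide <- attr(res, "wide")
  expect_identical(unname(wide["a", "7"]), 3L)
  expect_identical(unname(wide["b", "7"]), 4L)
})

test_that("decomposition CSV and figure are written", {
  ids <- paste0("s", 1:6)
  groups <- make_groups(ids, rep(c("a", "b"), each = 3))
  asg <- list("2" = setNames(rep(1:2, 3), ids),
              "3" = setNames(c(1L, 2L, 3L, 1L, 2L, 3L), ids))
  res <- decomposition(asg, groups)
  csv <- withr::local_tempfile(fileext = ".csv")
  fig <- withr::local_tempfile(fileext = ".png")
  write_decomposition(res, csv, fig)
  expect_identical(nrow(read.csv(csv)), 4L)
  expect_gt(file.size(fig), 0)
})
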