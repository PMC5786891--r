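# K-means over power spectra, exactly as the method runs it: random initial
# labels, alternate assignment / centroid-mean steps, Euclidean metric,
# many independent restarts, keep the restart with the smallest total
# within-cluster sum of squared distances.
#
# This is deliberately not stats::kmeans(): initialization is by random
# *labels* (not by sampling centers), restarts use reproducible derived
# seeds, every restart logs its objective trace, and empty clusters are
# repaired by reseeding to the farthest point.

# Squared Euclidean distances between rows of x (m x n) and rows of c (k x n).
.sq_dist <- function(x, centers) {
  xs <- rowSums(x^2)
  cs <- rowSums(centers^2)
  d2 <- outer(xs, cs, "+") - 2 * x %*% t(centers)
  d2[d2 < 0] <- 0  # numeric guard
  d2
}

.as_spectra_matrix <- function(spectra) {
  if (inherits(spectra, "spectrum_set")) spectra$spectra
  else as.matrix(spectra)
}

#' Single K-means run from a random label assignment
#'
#' Starts from uniformly random labels guaranteed to use all `k` clusters,
#' then alternates centroid-update (centroid = mean of assigned spectra)
#' and assignment (nearest centroid by Euclidean distance, ties to the
#' lowest cluster index) until the labels stop changing or `max_iter` is
#' reached.  If an update step finds a cluster empty, its centroid is
#' reseeded to the point farthest from the cluster's previous centroid and
#' that point is moved into the cluster.
#'
#' Uses the caller's RNG state unless `seed` is given.
#'
#' @param spectra A `spectrum_set` or numeric matrix (rows = observations).
#' @param k Number of clusters, `1 <= k <= m`.
#' @param max_iter Maximum (update, assign) iterations (default 300).
#' @param seed Optional integer seed for this run.
#' @return A `cluster_model`: list with `k`, `centroids` (k x n), `labels`
#'   (1-based, length m), `objective` (total within-cluster sum of squared
#'   Euclidean distances), `distances` (per-observation distance to its
#'   centroid), `n_iter`, `trace` (objective after each iteration),
#'   `converged`.
#' @export
kmeans_single <- function(spectra, k, max_iter = 300L, seed = NULL) {
  x <- .as_spectra_matrix(spectra)
  m <- nrow(x)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > m) stop("k = ", k, " exceeds the number of observations m = ", m,
                  call. = FALSE)
  if (max_iter < 1L) stop("max_iter must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))

  # random initial labels, all k guaranteed present
  labels <- sample(c(seq_len(k), sample.int(k, m - k, replace = TRUE)))

  centers <- matrix(0, nrow = k, ncol = ncol(x))
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # update step: centroid = mean of members; repair empty clusters
    counts <- tabulate(labels, nbins = k)
    sums <- rowsum(x, labels)  # one row per label present, sorted
    present <- as.integer(rownames(sums))
    centers[present, ] <- sums / counts[present]
    if (length(present) < k) {
      for (j in setdiff(seq_len(k), present)) {
        far <- which.max(colSums((t(x) - centers[j, ])^2))
        centers[j, ] <- x[far, ]
        labels[far] <- j
      }
    }
    # assignment step
    d2 <- .sq_dist(x, centers)
    new_labels <- max.col(-d2, ties.method = "first")
    trace <- c(trace, sum(d2[cbind(seq_len(m), new_labels)]))
    if (identical(new_labels, labels)) {
      converged <- TRUE
      break
    }
    labels <- new_labels
  }

  # canonical final state: centroids are exact means of the final labels
  counts <- tabulate(labels, nbins = k)
  sums <- rowsum(x, labels)
  present <- as.integer(rownames(sums))
  centers[present, ] <- sums / counts[present]
  d2 <- .sq_dist(x, centers)
  dist_own <- d2[cbind(seq_len(m), labels)]
  rownames(centers) <- paste0("C-", seq_len(k))
  structure(list(k = k,
                 centroids = centers,
                 labels = labels,
                 objective = sum(dist_own),
                 distances = sqrt(dist_own),
                 n_iter = iter,
                 trace = trace,
                 converged = converged),
            class = "cluster_model")
}

#' Multi-restart K-means over spectra
#'
#' Runs [kmeans_single()] `restarts` times from independent random label
#' initializations (per-restart seeds derived deterministically from the
#' master `seed`) and returns the model with the smallest objective; ties go
#' to the earliest restart.  The default of 50 restarts reflects the
#' method's standard setting.
#'
#' @inheritParams kmeans_single
#' @param restarts Number of independent restarts (default 50).
#' @param seed Master integer seed; required for reproducibility.
#' @return The best `cluster_model`, augmented with `n_restarts`, `seed`,
#'   `restart_objectives`, `n_iter_per_restart` and `restart_traces` (list
#'   of per-restart objective traces).
#' @export
kmeans_fit <- function(spectra, k, restarts = 50L, seed = 1L,
                       max_iter = 300L) {
  restarts <- as.integer(restarts)
  if (restarts < 1L) stop("restarts must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  restart_seeds <- sample.int(.Machine$integer.max, restarts)
  best <- NULL
  objectives <- numeric(restarts)
  iters <- integer(restarts)
  traces <- vector("list", restarts)
  for (r in seq_len(restarts)) {
    fit <- kmeans_single(spectra, k, max_iter = max_iter,
                         seed = restart_seeds[[r]])
    objectives[[r]] <- fit$objective
    iters[[r]] <- fit$n_iter
    traces[[r]] <- fit$trace
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  best$n_restarts <- restarts
  best$seed <- as.integer(seed)
  best$restart_objectives <- objectives
  best$n_iter_per_restart <- iters
  best$restart_traces <- traces
  best
}

#' Total within-cluster sum of squared distances
#'
#' Recomputes the K-means objective of a fitted model on a spectrum set:
#' the sum over observations of the squared Euclidean distance to the
#' centroid of the assigned cluster.
#'
#' @param spectra A `spectrum_set` or matrix the model was fitted on.
#' @param model A `cluster_model`.
#' @return Nonnegative scalar.
#' @export
objective <- function(spectra, model) {
  x <- .as_spectra_matrix(spectra)
  if (nrow(x) != length(model$labels)) {
    stop("model labels (", length(model$labels),
         ") do not cover the spectra rows (", nrow(x), ")", call. = FALSE)
  }
  if (ncol(x) != ncol(model$centroids)) {
    stop("spectra and centroids have different dimensions", call. = FALSE)
  }
  diffs <- x - model$centroids[model$labels, , drop = FALSE]
  sum(diffs^2)
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("cluster_model: k =", x$k, "on", length(x$labels), "observations\n")
  cat("  objective:", format(x$objective), "\n")
  if (!is.null(x$n_restarts)) {
    cat("  restarts:", x$n_restarts, "(seed", x$seed, ")\n")
  }
  cat("  cluster sizes:", paste(tabulate(x$labels, x$k), collapse = " "),
      "\n")
  invisible(x)
}

#' Relabel a model's clusters in radial-layout order
#'
#' Renumbers clusters so that cluster 1 is the one closest to the main
#' centroid (the unweighted mean of the centroids), cluster 2 the next, and
#' so on — the same order in which the radial plot assigns angles.  Output
#' labels `C-1 ... C-k` in assignment tables then match the plot.
#'
#' @param model A `cluster_model`.
#' @return The model with clusters renumbered; objective is unchanged.
#' @export
relabel_by_distance <- function(model) {
  M <- main_centroid(model)
  d <- sqrt(colSums((t(model$centroids) - M)^2))
  ord <- order(d, seq_len(model$k))          # ties by original index
  perm <- integer(model$k)
  perm[ord] <- seq_len(model$k)              # old label -> new label
  model$centroids <- model$centroids[ord, , drop = FALSE]
  rownames(model$centroids) <- paste0("C-", seq_len(model$k))
  model$labels <- perm[model$labels]
  model
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two label vectors over the same
#' items; 1 means identical partitions up to label permutation, values near
#' 0 mean chance-level agreement.
#'
#' @param a,b Label vectors (any atomic type) of equal length.
#' @return Scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
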