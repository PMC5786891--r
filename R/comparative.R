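# Evaluation analyses: how known groups decompose over clusters as k
# grows, and how discovered centroids compare with reference centroids
# built from the true groups.

#' Group decomposition across cluster counts
#'
#' For each clustering (one per value of k) and each group at the chosen
#' level, counts how many distinct clusters contain at least one member of
#' the group.  A group whose count stays at 1 while k grows is held
#' together by the clustering; fast-growing counts mean the group is being
#' split early.
#'
#' @param assignments Named list mapping each k (names are the k values) to
#'   a label vector named by sequence id, e.g. built from
#'   [kmeans_fit()] labels with `setNames(model$labels, ids)`.
#' @param groups A `group_table` covering the same ids.
#' @param level Group level to decompose (default: first level).
#' @return Object of class `decomposition_result`: data frame with columns
#'   `k`, `group`, `n_clusters`, plus a `wide` attribute (groups x k
#'   matrix).
#' @export
decomposition <- function(assignments, groups, level = NULL) {
  if (length(assignments) == 0L) stop("no assignments given", call. = FALSE)
  lev <- attr(groups, "levels")
  if (is.null(level)) level <- lev[[1]]
  rows <- list()
  for (kname in names(assignments)) {
    labels <- assignments[[kname]]
    ids <- names(labels)
    if (is.null(ids) || !setequal(ids, groups$id)) {
      stop("assignment ids for k = ", kname,
           " do not match the group table", call. = FALSE)
    }
    glab <- group_labels(groups, ids, level)
    for (g in unique(glab)) {
      rows[[length(rows) + 1L]] <- data.frame(
        k = as.integer(kname), group = g,
        n_clusters = length(unique(labels[glab == g])),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$k, out$group), ]
  rownames(out) <- NULL
  wide <- stats::xtabs(n_clusters ~ group + k, data = out)
  structure(out, wide = wide, class = c("decomposition_result",
                                        "data.frame"))
}

#' Reference centroids from true group labels
#'
#' Mean spectrum of each group at the chosen level — the "true" centroid a
#' perfect clustering of that group would discover.
#'
#' @param spectra A `spectrum_set` (or matrix with rownames = ids).
#' @param groups A `group_table` covering the spectra ids.
#' @param level Group level (default: first level).
#' @return Matrix with one row per non-empty group (rownames = group
#'   labels); empty groups are skipped with a warning.
#' @export
reference_centroids <- function(spectra, groups, level = NULL) {
  x <- .as_spectra_matrix(spectra)
  ids <- rownames(x)
  glab <- group_labels(groups, ids, level)
  lev_groups <- unique(glab)
  declared <- unique(groups[[if (is.null(level)) attr(groups, "levels")[[1]]
                             else level]])
  empty <- setdiff(declared, lev_groups)
  if (length(empty) > 0L) {
    warning("skipping empty group(s): ", paste(empty, collapse = ", "),
            call. = FALSE)
  }
  refs <- rowsum(x, glab) / as.vector(table(glab)[sort(lev_groups)])
  refs[lev_groups, , drop = FALSE]
}

#' Mean squared distances of cluster members to candidate centroids
#'
#' For each discovered cluster j, computes the mean over its member spectra
#' of the squared Euclidean distance to (a) the cluster's own centroid
#' (first column, `own`) and (b) each reference group centroid.  For
#' well-separated groups recovered correctly, each cluster's smallest
#' reference column is its own group, and the `own` column is the row
#' minimum.
#'
#' @param spectra A `spectrum_set` or matrix the model was fitted on.
#' @param model A `cluster_model`.
#' @param refs Reference centroid matrix from [reference_centroids()].
#' @return Object of class `reference_comparison`: list with `msd`
#'   (clusters x (1 + groups) matrix, first column `own`) and
#'   `centroid_distances` (clusters x groups Euclidean distances between
#'   centroids themselves).
#' @export
msd_matrix <- function(spectra, model, refs) {
  x <- .as_spectra_matrix(spectra)
  if (ncol(refs) != ncol(model$centroids)) {
    stop("reference centroids and model centroids differ in dimension",
         call. = FALSE)
  }
  k <- model$k
  cand <- rbind(own = rep(NA_real_, ncol(x)), refs)  # placeholder row
  msd <- matrix(NA_real_, nrow = k, ncol = 1L + nrow(refs),
                dimnames = list(paste0("C-", seq_len(k)),
                                c("own", rownames(refs))))
  for (j in seq_len(k)) {
    members <- x[model$labels == j, , drop = FALSE]
    cand[1, ] <- model$centroids[j, ]
    d2 <- .sq_dist(members, cand)
    msd[j, ] <- colMeans(d2)
  }
  cd <- sqrt(.sq_dist(model$centroids, refs))
  dimnames(cd) <- list(paste0("C-", seq_len(k)), rownames(refs))
  structure(list(msd = msd, centroid_distances = cd),
            class = "reference_comparison")
}

#' @export
print.reference_comparison <- function(x, ...) {
  cat("mean squared distances (clusters x centroids):\n")
  print(signif(x$msd, 4))
  invisible(x)
}

#' Write a decomposition result (CSV) and optionally a line figure
#'
#' @param result A `decomposition_result`.
#' @param path CSV output path.
#' @param plot_path Optional PNG/SVG path for a counts-vs-k line figure.
#' @return Invisibly, `path`.
#' @export
write_decomposition <- function(result, path, plot_path = NULL) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE,
                   quote = FALSE)
  if (!is.null(plot_path)) {
    wide <- attr(result, "wide")
    ext <- tolower(tools::file_ext(plot_path))
    if (ext == "png") grDevices::png(plot_path, 800, 600)
    else if (ext == "svg") grDevices::svg(plot_path, 8, 6)
    else stop("unsupported plot format '", ext, "'", call. = FALSE)
    on.exit(grDevices::dev.off())
    ks <- as.integer(colnames(wide))
    cols <- .group_palette(nrow(wide))
    graphics::matplot(ks, t(wide), type = "b", pch = 19, lty = 1,
                      col = cols, xlab = "number of clusters k",
                      ylab = "distinct clusters containing the group",
                      main = "Group decomposition vs k")
    graphics::legend("topleft", legend = rownames(wide), col = cols,
                     pch = 19, lty = 1, bty = "n")
  }
  invisible(path)
}
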