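# Radial 2-D visualization of a spectral clustering.
#
# The main centroid (unweighted mean of the k cluster centroids) sits at
# the origin.  Cluster centroids are sorted by their spectral distance to
# the main centroid and placed on a circle of evenly spaced angles at those
# distances; each sequence is placed around its own centroid at its
# spectral distance, with angles evenly spaced by within-cluster distance
# rank.  Radii are therefore true Euclidean distances in spectrum space:
# compact clusters draw compact.

#' Main centroid of a cluster model
#'
#' The unweighted element-wise mean of the k cluster centroids (not of the
#' m sequences), used as the origin of the radial plot.
#'
#' @param model A `cluster_model`.
#' @return Numeric n-vector.
#' @export
main_centroid <- function(model) {
  colMeans(model$centroids)
}

#' Polar coordinates of cluster centroids around the main centroid
#'
#' Computes each centroid's Euclidean distance `d` to the main centroid,
#' sorts clusters by `d` ascending (ties by original cluster index), and
#' assigns the sorted index `iota = 0 ... k-1` the angle
#' `theta = iota * 2 * pi / k`.
#'
#' @param model A `cluster_model`.
#' @param M Main centroid (defaults to [main_centroid()] of the model).
#' @return Data frame with one row per cluster in sorted order: `cluster`
#'   (original 1-based id), `iota`, `d`, `theta`.
#' @export
centroid_polar <- function(model, M = main_centroid(model)) {
  d <- sqrt(colSums((t(model$centroids) - M)^2))
  ord <- order(d, seq_len(model$k))
  data.frame(cluster = ord,
             iota = seq_len(model$k) - 1L,
             d = d[ord],
             theta = (seq_len(model$k) - 1L) * 2 * pi / model$k)
}

#' Radial layout coordinates for a fitted clustering
#'
#' Builds the full set of 2-D plot coordinates: cluster centroids at
#' `(d * cos(theta), d * sin(theta))` around the origin, and each sequence
#' at `(delta * cos(theta_z) + x_c, delta * sin(theta_z) + y_c)` around its
#' centroid, where `delta` is the sequence's spectral distance to its
#' centroid and `theta_z = rank * 2 * pi / cluster_size` with ranks ordered
#' by `delta` ascending (ties by input order).
#'
#' @param model A `cluster_model` fitted on `spectra`.
#' @param spectra The `spectrum_set` (or matrix) the model was fitted on.
#' @return Object of class `radial_layout`: list with `main_centroid`,
#'   `clusters` (cluster, iota, d, theta, x, y) and `sequences`
#'   (id, cluster, delta, theta, x, y).
#' @export
radial_layout <- function(model, spectra) {
  x <- .as_spectra_matrix(spectra)
  m <- nrow(x)
  if (m != length(model$labels)) {
    stop("model labels do not match the spectra rows", call. = FALSE)
  }
  if (any(model$labels < 1L | model$labels > model$k)) {
    stop("sequence label outside the model's clusters", call. = FALSE)
  }
  ids <- if (!is.null(rownames(x))) rownames(x) else paste0("seq", seq_len(m))

  M <- main_centroid(model)
  cl <- centroid_polar(model, M)
  cl$x <- cl$d * cos(cl$theta)
  cl$y <- cl$d * sin(cl$theta)

  delta <- sqrt(rowSums((x - model$centroids[model$labels, ,
                                             drop = FALSE])^2))
  seq_rows <- vector("list", model$k)
  for (i in seq_len(nrow(cl))) {
    j <- cl$cluster[[i]]
    members <- which(model$labels == j)
    members <- members[order(delta[members], members)]  # ties by input order
    mj <- length(members)
    theta_z <- (seq_len(mj) - 1L) * 2 * pi / mj
    seq_rows[[i]] <- data.frame(
      id = ids[members],
      cluster = j,
      delta = delta[members],
      theta = theta_z,
      x = delta[members] * cos(theta_z) + cl$x[[i]],
      y = delta[members] * sin(theta_z) + cl$y[[i]],
      stringsAsFactors = FALSE)
  }
  structure(list(main_centroid = M,
                 clusters = cl,
                 sequences = do.call(rbind, seq_rows)),
            class = "radial_layout")
}

#' @export
print.radial_layout <- function(x, ...) {
  cat("radial_layout:", nrow(x$clusters), "clusters,",
      nrow(x$sequences), "sequences\n")
  invisible(x)
}

#' Export layout coordinates as CSV
#'
#' One row per cluster centroid (`type = "cluster"`, radius = distance to
#' the main centroid) and per sequence (`type = "sequence"`, radius =
#' distance to the cluster centroid).
#'
#' @param layout A `radial_layout`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_layout <- function(layout, path) {
  cl <- layout$clusters
  sq <- layout$sequences
  df <- rbind(
    data.frame(type = "cluster", id = paste0("C-", cl$cluster),
               cluster = cl$cluster, radius = cl$d, theta = cl$theta,
               x = cl$x, y = cl$y, stringsAsFactors = FALSE),
    data.frame(type = "sequence", id = sq$id, cluster = sq$cluster,
               radius = sq$delta, theta = sq$theta, x = sq$x, y = sq$y,
               stringsAsFactors = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# palette for group styling; recycled with a warning if exceeded
.group_palette <- function(n) {
  base <- grDevices::hcl.colors(max(n, 3L), palette = "Dark 3")
  base[seq_len(n)]
}

#' Render a radial layout to an image file
#'
#' Draws the main centroid at the origin, cluster centroids labeled
#' `C-1 ... C-k` in sorted (angular) order, and all sequences.  If a
#' `group_table` is supplied, sequences are colored by their label at the
#' first (or given) group level; unknown labels fall back to grey with a
#' warning.  Output format (PNG or SVG) follows the file extension.
#'
#' @param layout A `radial_layout`.
#' @param groups Optional `group_table` for styling.
#' @param path Output file ending in `.png` or `.svg`.
#' @param level Group level used for coloring (default: first level).
#' @param width,height Device size in pixels (PNG) or inches (SVG).
#' @return Invisibly, `path`.
#' @export
render_layout <- function(layout, groups = NULL, path, level = NULL,
                          width = NULL, height = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    grDevices::png(path, width = width %||% 900, height = height %||% 900)
  } else if (ext == "svg") {
    grDevices::svg(path, width = width %||% 9, height = height %||% 9)
  } else {
    stop("unsupported plot format '", ext, "' (use .png or .svg)",
         call. = FALSE)
  }
  on.exit(grDevices::dev.off())

  cl <- layout$clusters
  sq <- layout$sequences
  col <- rep("grey40", nrow(sq))
  legend_labels <- NULL
  legend_cols <- NULL
  if (!is.null(groups)) {
    labels <- group_labels(groups, sq$id, level)
    uniq <- unique(labels)
    pal <- .group_palette(length(uniq))
    names(pal) <- uniq
    col <- unname(pal[labels])
    col[is.na(col)] <- "grey40"
    legend_labels <- uniq
    legend_cols <- pal
  }
  lim <- range(c(sq$x, sq$y, cl$x, cl$y, 0))
  lim <- lim + c(-0.08, 0.08) * diff(lim)
  graphics::plot(NA, xlim = lim, ylim = lim, asp = 1,
                 xlab = "", ylab = "", axes = FALSE,
                 main = sprintf("Spectral clusters (k = %d)", nrow(cl)))
  graphics::segments(0, 0, cl$x, cl$y, col = "grey80", lty = 3)
  graphics::points(sq$x, sq$y, pch = 21, bg = col, col = "grey20",
                   cex = 1.1)
  graphics::points(0, 0, pch = 3, cex = 2, lwd = 2)
  graphics::points(cl$x, cl$y, pch = 23, bg = "white", cex = 1.6, lwd = 2)
  graphics::text(cl$x, cl$y, labels = paste0("C-", cl$cluster),
                 pos = 3, offset = 0.6, font = 2)
  if (!is.null(legend_labels)) {
    graphics::legend("topright", legend = legend_labels, pt.bg = legend_cols,
                     pch = 21, bty = "n", cex = 0.9)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
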