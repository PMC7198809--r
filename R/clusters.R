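#' Per-sign thresholding of a discriminative weight map
#'
#' Positive and negative weights are thresholded separately: a voxel enters
#' the positive mask when `w >= fraction * max(w)` (over positive voxels) and
#' the negative mask when `w <= fraction * min(w)` (over negative voxels).
#' Thresholding per sign — rather than against the global absolute maximum —
#' keeps weaker but internally consistent positive clusters when the single
#' strongest weight happens to be negative.
#'
#' @param weights A [scalar_volume()] weight map (e.g. from
#'   [average_weight_map()]).
#' @param fraction Threshold fraction in (0, 1); the conventional report uses
#'   0.10.
#' @return List of two logical arrays, `positive` and `negative` (both empty
#'   for an all-zero map).
#' @export
threshold_map <- function(weights, fraction = 0.10) {
  stopifnot(inherits(weights, "scalar_volume"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("parameter error: fraction must lie in (0, 1)", call. = FALSE)
  w <- weights$values
  w[!is.finite(w)] <- 0  # out-of-mask NaN fills never survive
  pos_max <- max(w); neg_min <- min(w)
  pos <- if (pos_max > 0) w >= fraction * pos_max else array(FALSE, dim(w))
  neg <- if (neg_min < 0) w <= fraction * neg_min else array(FALSE, dim(w))
  list(positive = pos, negative = neg)
}

neighbour_offsets <- function(connectivity = 26L) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  switch(as.character(connectivity),
         "6"  = g[rowSums(abs(g)) == 1, , drop = FALSE],
         "18" = g[rowSums(abs(g)) <= 2, , drop = FALSE],
         "26" = g,
         stop("connectivity must be 6, 18 or 26", call. = FALSE))
}

#' Connected components of a voxel mask
#'
#' Partitions the true voxels into maximal connected components (default
#' 26-connectivity, the common neuroimaging reporting convention; 6 and 18
#' are available). Components are labelled deterministically: by descending
#' size, ties broken by the first member voxel in scan order.
#'
#' @param mask Logical 3-D array.
#' @param connectivity 6, 18 or 26.
#' @return List with `labels` (integer array, 0 = background), `sizes`
#'   (voxels per cluster, label order) and `n_clusters`.
#' @export
connected_clusters <- function(mask, connectivity = 26L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  d <- dim(mask)
  lin <- which(mask)
  labels <- array(0L, d)
  if (length(lin) == 0L)
    return(list(labels = labels, sizes = integer(0), n_clusters = 0L))
  rank_of <- array(0L, d)
  rank_of[lin] <- seq_along(lin)
  coords <- arrayInd(lin, d)
  offs <- neighbour_offsets(connectivity)
  edges <- list()
  for (t in seq_len(nrow(offs))) {
    nb <- coords + matrix(offs[t, ], nrow(coords), 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] + (nb[ok, 3] - 1L) * d[1] * d[2]
    r <- rank_of[nb_lin]
    keep <- r > 0L
    if (any(keep))
      edges[[length(edges) + 1L]] <- cbind(which(ok)[keep], r[keep])
  }
  g <- igraph::make_empty_graph(n = length(lin), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  memb <- igraph::components(g)$membership
  # relabel: descending size, ties by first member voxel in scan order
  sizes0 <- tabulate(memb)
  first0 <- vapply(seq_along(sizes0), function(cl) min(which(memb == cl)), integer(1))
  ord <- order(-sizes0, first0)
  relabel <- integer(length(sizes0)); relabel[ord] <- seq_along(ord)
  labels[lin] <- relabel[memb]
  list(labels = labels, sizes = sizes0[ord], n_clusters = length(ord))
}

#' Cluster report of a discriminative weight map
#'
#' Thresholds the map per sign ([threshold_map()]), extracts connected
#' clusters, drops those smaller than `min_size` voxels (inclusive `>=`
#' filter; the conventional report keeps clusters of 20 voxels and larger),
#' and tabulates size, signed peak weight and peak coordinate. Rows are
#' grouped by sign (positive first: regions where the patients' values are
#' lower) and sorted within sign by descending absolute peak weight — the
#' contribution order.
#'
#' @param weights A [scalar_volume()] weight map.
#' @param fraction Per-sign threshold fraction (default 0.10).
#' @param min_size Minimum cluster size in voxels (default 20).
#' @param connectivity Cluster connectivity (default 26).
#' @return A data frame of class `cluster_table`: `cluster_id`, `sign`,
#'   `size`, `peak_weight`, voxel coordinates `x`, `y`, `z` (1-based), and
#'   world-space `mni_x/y/z` columns when the map carries an affine.
#' @export
cluster_table <- function(weights, fraction = 0.10, min_size = 20L,
                          connectivity = 26L) {
  stopifnot(inherits(weights, "scalar_volume"))
  if (min_size < 1L) stop("parameter error: min_size must be >= 1", call. = FALSE)
  masks <- threshold_map(weights, fraction)
  w <- weights$values
  w[!is.finite(w)] <- 0
  rows <- list()
  for (sgn in c("positive", "negative")) {
    cc <- connected_clusters(masks[[sgn]], connectivity)
    if (cc$n_clusters == 0L) next
    for (cl in seq_len(cc$n_clusters)) {
      if (cc$sizes[cl] < min_size) next
      lin <- which(cc$labels == cl)
      peak_lin <- lin[which.max(abs(w[lin]))]  # first in scan order on ties
      pc <- arrayInd(peak_lin, dim(w))
      rows[[length(rows) + 1L]] <- data.frame(
        sign = sgn, size = cc$sizes[cl], peak_weight = w[peak_lin],
        x = pc[1], y = pc[2], z = pc[3])
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(cluster_id = integer(0), sign = character(0),
                      size = integer(0), peak_weight = numeric(0),
                      x = integer(0), y = integer(0), z = integer(0))
    class(out) <- c("cluster_table", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$sign != "positive", -abs(out$peak_weight)), , drop = FALSE]
  out <- cbind(cluster_id = seq_len(nrow(out)), out)
  if (!is.null(weights$affine)) {
    vox0 <- t(rbind(out$x - 1, out$y - 1, out$z - 1, 1))  # affine maps 0-based indices
    world <- vox0 %*% t(weights$affine)
    out$mni_x <- world[, 1]; out$mni_y <- world[, 2]; out$mni_z <- world[, 3]
  }
  rownames(out) <- NULL
  class(out) <- c("cluster_table", "data.frame")
  out
}
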