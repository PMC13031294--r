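# From-scratch DBSCAN over an explicit pairwise-distance formulation.
# Intended to run on small point sets (typically the k centroids produced
# by kmeans_fit, where k << n), so neighbourhoods are computed from the
# full distance matrix rather than a spatial index.
#
# Typing convention: a point is *core* when its eps-neighbourhood
# (including the point itself) holds at least min_pts points; a non-core
# point within eps of a core point is *border* and inherits the cluster of
# its lowest-index core neighbour (deterministic tie-break); everything
# else is *noise*. Clusters are the connected components of the graph on
# core points with edges between core points within eps, numbered 1..C in
# order of their first core point; noise carries label 0.

#' Density parameters
#'
#' Validates and bundles the DBSCAN neighbourhood radius and density
#' threshold.
#'
#' @param eps Neighbourhood radius (> 0, Euclidean feature-space units).
#' @param min_pts Minimum neighbourhood size (including the point itself)
#'   for the core-point criterion (integer >= 1).
#' @return An object of class `density_params`.
#' @export
density_params <- function(eps, min_pts) {
  if (!is.numeric(eps) || length(eps) != 1L || !is.finite(eps) || eps <= 0) {
    stop_invalid("`eps` must be a single positive number")
  }
  min_pts <- check_count(min_pts, "min_pts", min = 1L)
  structure(list(eps = as.numeric(eps), min_pts = min_pts), class = "density_params")
}

as_density_params <- function(params) {
  if (inherits(params, "density_params")) return(params)
  if (is.list(params) && all(c("eps", "min_pts") %in% names(params))) {
    return(density_params(params$eps, params$min_pts))
  }
  stop_invalid("`params` must be a density_params object (see density_params())")
}

points_matrix <- function(x) {
  if (inherits(x, "point_set")) x <- x$points
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop_invalid("input points must be finite")
  x
}

# Connected components of an undirected graph given as a logical adjacency
# matrix, by iterative breadth-first search; returns a component id per
# vertex, numbered in order of first appearance.
bfs_components <- function(adj) {
  m <- nrow(adj)
  comp <- integer(m)
  current <- 0L
  for (s in seq_len(m)) {
    if (comp[s] != 0L) next
    current <- current + 1L
    frontier <- s
    comp[s] <- current
    while (length(frontier) > 0L) {
      nbr <- which(matrixStats_any_col(adj, frontier))
      nbr <- nbr[comp[nbr] == 0L]
      comp[nbr] <- current
      frontier <- nbr
    }
  }
  comp
}

# column-wise "any" over selected rows without forming large intermediates
matrixStats_any_col <- function(adj, rows) {
  if (length(rows) == 1L) adj[rows, ] else colSums(adj[rows, , drop = FALSE]) > 0
}

#' DBSCAN with explicit core/border/noise typing
#'
#' Runs density-based clustering on a point set using exhaustive Euclidean
#' neighbourhood counting. Clusters are the connected components of the
#' core-point graph; border points take the cluster of their lowest-index
#' core neighbour; noise points get label 0.
#'
#' @param x A [point_set] or numeric matrix (m x d).
#' @param params A [density_params] object (or list with `eps`, `min_pts`).
#' @return An object of class `dbscan_result`: `labels` (0 = noise,
#'   clusters 1..C), `point_type` (character, "core"/"border"/"noise"),
#'   `neighbor_counts` (eps-neighbourhood sizes, self included),
#'   `n_clusters`, `params`.
#' @examples
#' r <- dbscan_fit(point_set(c(0, 1, 2, 10, 11, 12, 50)),
#'                 density_params(eps = 1.5, min_pts = 3))
#' r$labels      # 1 1 1 2 2 2 0
#' r$point_type  # border core border border core border noise
#' @export
dbscan_fit <- function(x, params) {
  x <- points_matrix(x)
  params <- as_density_params(params)
  m <- nrow(x)

  d <- as.matrix(stats::dist(x))
  within <- d <= params$eps
  counts <- as.integer(rowSums(within))
  core <- counts >= params$min_pts

  labels <- integer(m)
  type <- rep("noise", m)
  if (any(core)) {
    type[core] <- "core"
    core_idx <- which(core)
    core_adj <- within[core_idx, core_idx, drop = FALSE]
    comp <- bfs_components(core_adj)
    labels[core_idx] <- comp

    non_core <- which(!core)
    for (i in non_core) {
      nbr_cores <- core_idx[within[i, core_idx]]
      if (length(nbr_cores) > 0L) {
        type[i] <- "border"
        labels[i] <- labels[min(nbr_cores)]
      }
    }
  }

  structure(list(
    labels = labels,
    point_type = type,
    neighbor_counts = counts,
    n_clusters = max(labels),
    params = params
  ), class = "dbscan_result")
}

#' @export
print.dbscan_result <- function(x, ...) {
  cat(sprintf(
    "dbscan_result: %d points, %d cluster(s) (eps = %g, min_pts = %d)\n  core %d | border %d | noise %d\n",
    length(x$labels), x$n_clusters, x$params$eps, x$params$min_pts,
    sum(x$point_type == "core"), sum(x$point_type == "border"),
    sum(x$point_type == "noise")))
  invisible(x)
}

#' Classify points as core, border or noise
#'
#' Per-point density typing by exhaustive neighbourhood counting, without
#' constructing the clusters: core points meet the min_pts criterion
#' (self-inclusive), border points are non-core points within eps of a
#' core point, and the remainder is noise. Consistent with the
#' `point_type` field of [dbscan_fit] on the same input.
#'
#' @inheritParams dbscan_fit
#' @return Character vector of "core"/"border"/"noise", one per point.
#' @export
classify_point_types <- function(x, params) {
  x <- points_matrix(x)
  params <- as_density_params(params)
  d <- as.matrix(stats::dist(x))
  within <- d <= params$eps
  core <- rowSums(within) >= params$min_pts
  type <- rep("noise", nrow(x))
  type[core] <- "core"
  if (any(core)) {
    near_core <- rowSums(within[, core, drop = FALSE]) > 0
    type[!core & near_core] <- "border"
  }
  type
}
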