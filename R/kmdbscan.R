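# The hybrid algorithm: compress n points to k centroids with k-means, run
# DBSCAN on the centroids (k << n makes the quadratic density step cheap),
# then hand each original point the density label of its centroid. Total
# cost O(nk + k^2) against O(n^2) for DBSCAN on the raw points.

#' Propagate centroid labels to original points
#'
#' Each original point receives the label of the centroid it is assigned
#' to. Noise centroids (label 0) propagate noise by default; with
#' `noise_to_nearest = TRUE` points on noise centroids are re-attached to
#' the nearest centroid carrying a non-noise label (requires `x`).
#'
#' @param model A `centroid_model` from [kmeans_fit].
#' @param centroid_labels Integer vector of length `model$k` (0 = noise).
#' @param noise_to_nearest Re-assign points of noise centroids to the
#'   nearest non-noise centroid (default `FALSE`).
#' @param x Original points (only needed when `noise_to_nearest = TRUE`).
#' @return Integer vector of length n with the propagated labels.
#' @export
propagate_labels <- function(model, centroid_labels, noise_to_nearest = FALSE, x = NULL) {
  stopifnot(inherits(model, "centroid_model"))
  centroid_labels <- as.integer(centroid_labels)
  if (length(centroid_labels) != model$k) {
    stop_invalid(sprintf("`centroid_labels` must have length k = %d, got %d",
                         model$k, length(centroid_labels)))
  }
  out <- centroid_labels[model$assignment]
  if (noise_to_nearest && any(out == 0L)) {
    keep <- centroid_labels != 0L
    if (!any(keep)) return(out)
    if (is.null(x)) stop_invalid("`x` is required when noise_to_nearest = TRUE")
    pts <- points_matrix(x)
    noisy <- which(out == 0L)
    d2 <- cross_dist2(pts[noisy, , drop = FALSE], model$centroids[keep, , drop = FALSE])
    nearest <- max.col(-d2, ties.method = "first")
    out[noisy] <- centroid_labels[keep][nearest]
  }
  out
}

#' KM-DBSCAN hybrid clustering
#'
#' Compresses the data to `k` k-means centroids, density-clusters the
#' centroids with DBSCAN, and propagates the centroid cluster labels back
#' to every original point. With `k = n` (distinct points) the result
#' degenerates to plain DBSCAN up to cluster renumbering.
#'
#' @param x A [point_set] or numeric matrix.
#' @param k Number of centroids (1 <= k <= n).
#' @param params A [density_params] object applied at the centroid level.
#' @param seed Integer RNG seed (drives the k-means initialisation; the
#'   density stage is deterministic).
#' @param noise_to_nearest Passed to [propagate_labels].
#' @return An object of class `km_dbscan`: `point_labels` (length n,
#'   0 = noise), `centroid_result` (a `dbscan_result` over the centroids),
#'   `model` (the `centroid_model`), `params`, `seed`.
#' @examples
#' rings <- make_concentric_rings(600, seed = 7)
#' fit <- km_dbscan(rings, k = 60, density_params(eps = 1.2, min_pts = 3), seed = 7)
#' table(fit$point_labels, rings$labels)
#' @export
km_dbscan <- function(x, k, params, seed = 1L, noise_to_nearest = FALSE) {
  pts <- points_matrix(x)
  params <- as_density_params(params)
  model <- kmeans_fit(pts, k = k, seed = seed)
  centroid_result <- dbscan_fit(model$centroids, params)
  point_labels <- propagate_labels(model, centroid_result$labels,
                                   noise_to_nearest = noise_to_nearest, x = pts)
  structure(list(
    point_labels = point_labels,
    centroid_result = centroid_result,
    model = model,
    params = params,
    seed = as.integer(seed)
  ), class = "km_dbscan")
}

#' @export
print.km_dbscan <- function(x, ...) {
  cat(sprintf(
    "km_dbscan: %d points -> %d centroids -> %d cluster(s); %d point(s) labelled noise\n",
    length(x$point_labels), x$model$k, x$centroid_result$n_clusters,
    sum(x$point_labels == 0L)))
  invisible(x)
}
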