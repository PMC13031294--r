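# From-scratch Lloyd k-means with k-means++ seeding. Written in-package
# (rather than calling stats::kmeans) because the downstream density stage
# depends on this exact contract: deterministic seeded initialisation,
# non-increasing inertia, empty-cluster re-seeding at the worst-fit point,
# and a stable point -> centroid assignment used for label propagation.

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, nrow = k, ncol = ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  if (k > 1L) {
    d2 <- cross_dist2(x, centers[1L, , drop = FALSE])[, 1L]
    for (j in 2L:k) {
      if (all(d2 == 0)) {
        # remaining mass is on already-chosen points: fall back to uniform
        idx <- sample.int(n, 1L)
      } else {
        idx <- sample.int(n, 1L, prob = d2)
      }
      centers[j, ] <- x[idx, ]
      d2 <- pmin(d2, cross_dist2(x, centers[j, , drop = FALSE])[, 1L])
    }
  }
  centers
}

#' Fit k-means centroids
#'
#' Lloyd iterations from a k-means++ seeding: assign each point to its
#' nearest centroid (Euclidean), recompute each centroid as the mean of its
#' assigned points, and stop when the largest centroid displacement falls
#' below `tol` or after `max_iter` sweeps. An emptied cluster is re-seeded
#' at the point currently farthest from its centroid, so every centroid
#' always has at least one assigned point. The within-cluster sum of
#' squares (inertia) is non-increasing across iterations.
#'
#' @param x A [point_set] or numeric matrix.
#' @param k Number of centroids, 1 <= k <= n.
#' @param seed Integer RNG seed (controls the k-means++ draw).
#' @param max_iter Maximum number of Lloyd sweeps (default 300).
#' @param tol Convergence tolerance on the maximum centroid displacement
#'   (default 1e-4, in feature units).
#' @return An object of class `centroid_model`: `centroids` (k x d),
#'   `assignment` (length-n integers in 1..k), `inertia`,
#'   `inertia_trace` (per-iteration values), `k`, `seed`, `iterations`,
#'   `converged`.
#' @examples
#' m <- kmeans_fit(point_set(c(0, 1, 10, 11)), k = 2, seed = 1)
#' sort(m$centroids[, 1])  # 0.5 10.5
#' @export
kmeans_fit <- function(x, k, seed = 1L, max_iter = 300L, tol = 1e-4) {
  if (inherits(x, "point_set")) x <- x$points
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop_invalid("input points must be finite")
  n <- nrow(x)
  k <- check_count(k, "k", min = 1L)
  if (k > n) stop_invalid(sprintf("`k` (%d) must not exceed the number of points (%d)", k, n))
  max_iter <- check_count(max_iter, "max_iter", min = 1L)
  if (!is.numeric(tol) || tol < 0) stop_invalid("`tol` must be non-negative")

  with_seed(seed, {
    centers <- kmeanspp_init(x, k)
    assignment <- integer(n)
    inertia_trace <- numeric(0)
    converged <- FALSE
    iter <- 0L
    repeat {
      iter <- iter + 1L
      d2 <- cross_dist2(x, centers)
      assignment <- max.col(-d2, ties.method = "first")
      point_d2 <- d2[cbind(seq_len(n), assignment)]

      # re-seed emptied clusters at the point worst served by its centroid;
      # -Inf masks points already used so duplicates never collapse clusters
      for (j in seq_len(k)) {
        if (!any(assignment == j)) {
          worst <- which.max(point_d2)
          assignment[worst] <- j
          centers[j, ] <- x[worst, ]
          point_d2[worst] <- -Inf
        }
      }
      inertia_trace <- c(inertia_trace, sum(pmax(point_d2, 0)))

      new_centers <- centers
      for (j in seq_len(k)) {
        members <- assignment == j
        new_centers[j, ] <- colMeans(x[members, , drop = FALSE])
      }
      shift <- sqrt(max(rowSums((new_centers - centers)^2)))
      centers <- new_centers
      if (shift < tol) {
        converged <- TRUE
        break
      }
      if (iter >= max_iter) break
    }
    # final assignment / inertia against the converged centroids
    d2 <- cross_dist2(x, centers)
    assignment <- max.col(-d2, ties.method = "first")
    point_d2 <- d2[cbind(seq_len(n), assignment)]
    for (j in seq_len(k)) {
      if (!any(assignment == j)) {
        worst <- which.max(point_d2)
        assignment[worst] <- j
        centers[j, ] <- x[worst, ]
        point_d2[worst] <- -Inf
      }
    }
    inertia <- sum(rowSums((x - centers[assignment, , drop = FALSE])^2))
    structure(list(
      centroids = centers,
      assignment = assignment,
      inertia = inertia,
      inertia_trace = inertia_trace,
      k = k,
      seed = as.integer(seed),
      iterations = iter,
      converged = converged
    ), class = "centroid_model")
  })
}

#' @export
print.centroid_model <- function(x, ...) {
  cat(sprintf("centroid_model: k = %d, inertia = %.6g, %d iteration(s)%s\n",
              x$k, x$inertia, x$iterations,
              if (x$converged) " (converged)" else " (max_iter reached)"))
  invisible(x)
}
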