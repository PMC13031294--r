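# Border-retention instance selection. Each class is processed
# independently: compress the class to k centroids, type each centroid as
# core / border / noise by density, and keep the border region — the part
# of the class that sits near decision boundaries — as the reduced
# training set. Core regions (dense interiors) and noise (outliers) are
# discarded. Selected items are always real original rows, mapped back by
# index; synthetic centroids never enter the reduced set.

#' Reduce dimensionality before clustering
#'
#' Projects the points to `d_prime` dimensions with row order preserved,
#' so row i of the embedding corresponds to row i of the input and
#' selected indices remain valid in the original space. PCA is delegated
#' to [stats::prcomp] with a fixed sign convention (the largest-magnitude
#' loading of each component is made positive) so results are
#' deterministic.
#'
#' @param x A [point_set] or numeric matrix.
#' @param method `"pca"` (supported) or `"umap"` (not available in this
#'   build; raises an error).
#' @param d_prime Target dimensionality, < d.
#' @param seed Integer RNG seed (kept in the signature for methods with a
#'   stochastic fit; PCA ignores it).
#' @return A [point_set] with `d_prime` columns, labels carried over.
#' @export
embed_points <- function(x, method = c("pca", "umap"), d_prime, seed = 1L) {
  method <- match.arg(method)
  labels <- if (inherits(x, "point_set")) x$labels else NULL
  pts <- points_matrix(x)
  d_prime <- check_count(d_prime, "d_prime", min = 1L)
  if (d_prime >= ncol(pts)) {
    stop_invalid(sprintf("`d_prime` (%d) must be smaller than the input dimension (%d)",
                         d_prime, ncol(pts)))
  }
  if (method == "umap") {
    stop_invalid("UMAP embedding is not available in this build; use method = \"pca\"")
  }
  pc <- stats::prcomp(pts, center = TRUE, scale. = FALSE, rank. = d_prime)
  rot <- pc$rotation
  flip <- apply(rot, 2L, function(v) sign(v[which.max(abs(v))]))
  emb <- sweep(pc$x[, seq_len(d_prime), drop = FALSE], 2L, flip, `*`)
  point_set(emb, labels = labels)
}

#' Reduce one class by border retention
#'
#' Applies the reduction to the points of a single class: fit `k_c`
#' centroids, type each centroid by density, and select original rows
#' according to `policy`:
#' \describe{
#'   \item{nearest_member}{one real representative per *border* centroid —
#'     the assigned point nearest to it (deduplicated). The default.}
#'   \item{all_members}{every point assigned to a border centroid.}
#'   \item{kmeans_only}{ablation: skip density typing, keep one nearest
#'     member per centroid (all k_c of them).}
#'   \item{dbscan_only}{ablation: skip compression, run DBSCAN on the raw
#'     class points and keep its border points.}
#' }
#' When no border centroid exists (all core because eps exceeds the
#' centroid-cloud diameter, or all noise because min_pts is unattainable)
#' the selection is empty and a warning is raised.
#'
#' @param x A [point_set] or matrix holding the points of one class.
#' @param k_c Centroid count for this class; clamped to the class size
#'   with a warning when larger.
#' @param params A [density_params] applied at the centroid level (or to
#'   raw points under `dbscan_only`).
#' @param policy Selection policy (see above).
#' @param seed Integer RNG seed.
#' @return A list: `selected` (sorted local row indices into `x`),
#'   `stats` (named counts: n, k, n_core, n_border, n_noise, n_selected).
#' @export
reduce_class <- function(x, k_c, params,
                         policy = c("nearest_member", "all_members",
                                    "kmeans_only", "dbscan_only"),
                         seed = 1L) {
  policy <- match.arg(policy)
  pts <- points_matrix(x)
  params <- as_density_params(params)
  n_c <- nrow(pts)
  k_c <- check_count(k_c, "k_c", min = 1L)
  if (k_c > n_c) {
    warning(sprintf("k_c (%d) exceeds class size (%d); clamped", k_c, n_c),
            call. = FALSE)
    k_c <- n_c
  }

  if (policy == "dbscan_only") {
    res <- dbscan_fit(pts, params)
    selected <- which(res$point_type == "border")
    stats <- c(n = n_c, k = n_c,
               n_core = sum(res$point_type == "core"),
               n_border = sum(res$point_type == "border"),
               n_noise = sum(res$point_type == "noise"),
               n_selected = length(selected))
    if (length(selected) == 0L) {
      warning("no border points found for this class; selection is empty",
              call. = FALSE)
    }
    return(list(selected = sort(selected), stats = stats))
  }

  model <- kmeans_fit(pts, k = k_c, seed = seed)

  if (policy == "kmeans_only") {
    selected <- nearest_members(pts, model, seq_len(k_c))
    stats <- c(n = n_c, k = k_c, n_core = 0L, n_border = k_c, n_noise = 0L,
               n_selected = length(selected))
    return(list(selected = sort(selected), stats = stats))
  }

  type <- classify_point_types(model$centroids, params)
  border_centroids <- which(type == "border")
  selected <- if (length(border_centroids) == 0L) {
    integer(0)
  } else if (policy == "nearest_member") {
    nearest_members(pts, model, border_centroids)
  } else {
    which(model$assignment %in% border_centroids)
  }
  if (length(selected) == 0L) {
    warning(sprintf(
      "no border centroids for this class (core: %d, noise: %d); selection is empty",
      sum(type == "core"), sum(type == "noise")), call. = FALSE)
  }
  stats <- c(n = n_c, k = k_c,
             n_core = sum(type == "core"),
             n_border = sum(type == "border"),
             n_noise = sum(type == "noise"),
             n_selected = length(selected))
  list(selected = sort(unique(selected)), stats = stats)
}

# For each listed centroid, the index of its nearest assigned point
# (deduplicated). Every centroid has >= 1 assigned point by the kmeans_fit
# contract.
nearest_members <- function(pts, model, centroid_ids) {
  sel <- vapply(centroid_ids, function(j) {
    members <- which(model$assignment == j)
    d2 <- cross_dist2(pts[members, , drop = FALSE],
                      model$centroids[j, , drop = FALSE])[, 1L]
    members[which.min(d2)]
  }, integer(1))
  unique(sel)
}

#' Reduction specification
#'
#' Bundles the parameters of [reduce_dataset]. Per-class settings are
#' given as named lists keyed by class label (as character); a single
#' unnamed value applies to every class. The centroid count per class is
#' either explicit (`per_class_k`) or derived from a fraction `alpha` as
#' `ceiling(alpha * n_class)`.
#'
#' @param per_class_k Named list/vector of centroid counts per class, or a
#'   single count for all classes. Mutually exclusive with `alpha`.
#' @param alpha Fraction in (0, 1\]; k_class = ceiling(alpha * n_class).
#' @param eps,min_pts Density parameters: single values or named
#'   lists/vectors per class.
#' @param embed_method `"none"` (default) or `"pca"`.
#' @param embed_dims Target dimensionality when embedding.
#' @param policy Selection policy, see [reduce_class].
#' @param standardize Standardize features (zero mean, unit variance)
#'   before clustering (default `FALSE`).
#' @param seed Integer RNG seed.
#' @return An object of class `reduction_spec`.
#' @export
reduction_spec <- function(per_class_k = NULL, alpha = NULL,
                           eps, min_pts,
                           embed_method = c("none", "pca", "umap"),
                           embed_dims = NULL,
                           policy = c("nearest_member", "all_members",
                                      "kmeans_only", "dbscan_only"),
                           standardize = FALSE,
                           seed = 1L) {
  embed_method <- match.arg(embed_method)
  policy <- match.arg(policy)
  if (is.null(per_class_k) && is.null(alpha)) {
    stop_invalid("one of `per_class_k` or `alpha` must be given")
  }
  if (!is.null(per_class_k) && !is.null(alpha)) {
    stop_invalid("`per_class_k` and `alpha` are mutually exclusive")
  }
  if (!is.null(alpha)) {
    if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
      stop_invalid("`alpha` must be a single value in (0, 1]")
    }
  }
  if (embed_method != "none" && is.null(embed_dims)) {
    stop_invalid("`embed_dims` is required when `embed_method` is not \"none\"")
  }
  structure(list(
    per_class_k = per_class_k, alpha = alpha,
    eps = eps, min_pts = min_pts,
    embed_method = embed_method, embed_dims = embed_dims,
    policy = policy, standardize = isTRUE(standardize),
    seed = as.integer(seed)
  ), class = "reduction_spec")
}

per_class_value <- function(spec_field, class_label, name) {
  key <- as.character(class_label)
  if (!is.null(names(spec_field))) {
    if (key %in% names(spec_field)) return(spec_field[[key]])
    stop_invalid(sprintf("no `%s` value for class %s", name, key))
  }
  if (length(spec_field) == 1L) return(spec_field[[1L]])
  stop_invalid(sprintf("no `%s` value for class %s", name, key))
}

#' Reduce a labelled dataset by per-class border retention
#'
#' Runs the full reduction pipeline: optional standardization and
#' dimensionality reduction (row order preserved), then [reduce_class] on
#' each class subset, and finally the union of per-class selections
#' mapped back to original row indices.
#'
#' @param x A [point_set] with class labels.
#' @param spec A [reduction_spec].
#' @return An object of class `reduction_result`: `selected_indices`
#'   (sorted unique original row indices), `per_class_stats` (data frame,
#'   one row per class), `reduction_ratio` (|selected| / n, exact),
#'   `spec`.
#' @examples
#' blobs <- make_gaussian_mixture(400, means = rbind(c(0, 0), c(8, 0)),
#'                                sds = 1, seed = 3)
#' spec <- reduction_spec(per_class_k = 20, eps = 1.4, min_pts = 3, seed = 3)
#' red <- reduce_dataset(blobs, spec)
#' red$reduction_ratio
#' @export
reduce_dataset <- function(x, spec) {
  stopifnot(inherits(spec, "reduction_spec"))
  if (!inherits(x, "point_set") || is.null(x$labels)) {
    stop_invalid("`x` must be a point_set with class labels")
  }
  pts <- x$points
  n <- nrow(pts)
  if (spec$standardize) {
    pts <- scale(pts)
    sds0 <- attr(pts, "scaled:scale") == 0
    if (any(sds0)) pts[, sds0] <- 0
    pts <- unclass(pts)
    attr(pts, "scaled:center") <- NULL
    attr(pts, "scaled:scale") <- NULL
  }
  work <- point_set(pts, labels = x$labels)
  if (spec$embed_method != "none") {
    work <- embed_points(work, method = spec$embed_method,
                         d_prime = spec$embed_dims, seed = spec$seed)
  }

  classes <- sort(unique(x$labels))
  selected_all <- integer(0)
  stats_rows <- vector("list", length(classes))
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    rows <- which(x$labels == cl)
    n_cl <- length(rows)
    k_cl <- if (!is.null(spec$alpha)) {
      as.integer(ceiling(spec$alpha * n_cl))
    } else {
      as.integer(per_class_value(spec$per_class_k, cl, "per_class_k"))
    }
    params <- density_params(per_class_value(spec$eps, cl, "eps"),
                             per_class_value(spec$min_pts, cl, "min_pts"))
    res <- reduce_class(work$points[rows, , drop = FALSE], k_c = k_cl,
                        params = params, policy = spec$policy,
                        seed = spec$seed + ci)
    selected_all <- c(selected_all, rows[res$selected])
    stats_rows[[ci]] <- data.frame(class = cl, t(res$stats))
  }
  selected_all <- sort(unique(selected_all))
  if (length(selected_all) == 0L) {
    warning("reduction produced an empty selection for every class", call. = FALSE)
  }
  structure(list(
    selected_indices = selected_all,
    per_class_stats = do.call(rbind, stats_rows),
    reduction_ratio = length(selected_all) / n,
    n = n,
    spec = spec
  ), class = "reduction_result")
}

#' @export
print.reduction_result <- function(x, ...) {
  cat(sprintf("reduction_result: %d of %d rows retained (reduction ratio %.4f)\n",
              length(x$selected_indices), x$n, x$reduction_ratio))
  print(x$per_class_stats, row.names = FALSE)
  invisible(x)
}

#' Grid-tune density parameters
#'
#' Exhaustively evaluates every (eps, min_pts) grid cell on a set of
#' points (typically centroids) and returns the best cell under the
#' chosen objective:
#' \describe{
#'   \item{ari_vs_labels}{maximise the adjusted Rand index of the DBSCAN
#'     clustering against `labels` (noise kept as its own label).}
#'   \item{border_fraction_target}{bring the fraction of border-typed
#'     points closest to `target`.}
#' }
#' Ties are broken toward smaller eps, then smaller min_pts.
#'
#' With `prefer_plateau = TRUE` (ARI objective only), instead of the raw
#' argmax the tuner restricts to cells scoring within `plateau_tol` of
#' the maximum, finds the longest contiguous run of eps values at a
#' single min_pts among them, and returns that run's central cell. This
#' mirrors how practitioners pick eps in the middle of a stable operating
#' plateau rather than at its edge, where a small perturbation can tip
#' the clustering over a merge/fragment boundary.
#'
#' @param x A [point_set] or matrix to cluster (centroids in the usual
#'   workflow).
#' @param eps_grid,min_pts_grid Non-empty numeric grids.
#' @param objective Tuning objective (see above).
#' @param labels Ground-truth labels, required for `ari_vs_labels`.
#' @param target Desired border fraction in \[0, 1\], required for
#'   `border_fraction_target`.
#' @param prefer_plateau Return the centre of the widest near-maximal eps
#'   plateau instead of the raw argmax (default `FALSE`).
#' @param plateau_tol Score slack defining "near-maximal" cells when
#'   `prefer_plateau = TRUE` (default 0.01).
#' @return A [density_params] with attributes `score` (objective value of
#'   the winning cell) and `grid` (data frame of all evaluated cells).
#' @export
tune_density_params <- function(x, eps_grid, min_pts_grid,
                                objective = c("ari_vs_labels", "border_fraction_target"),
                                labels = NULL, target = NULL,
                                prefer_plateau = FALSE, plateau_tol = 0.01) {
  objective <- match.arg(objective)
  pts <- points_matrix(x)
  if (length(eps_grid) == 0L || length(min_pts_grid) == 0L) {
    stop_invalid("`eps_grid` and `min_pts_grid` must be non-empty")
  }
  if (objective == "ari_vs_labels") {
    if (is.null(labels) && inherits(x, "point_set")) labels <- x$labels
    if (is.null(labels)) stop_invalid("`labels` are required for objective = \"ari_vs_labels\"")
  } else {
    if (is.null(target) || target < 0 || target > 1) {
      stop_invalid("`target` in [0, 1] is required for objective = \"border_fraction_target\"")
    }
  }
  grid <- expand.grid(eps = sort(as.numeric(eps_grid)),
                      min_pts = sort(as.integer(min_pts_grid)))
  grid <- grid[order(grid$eps, grid$min_pts), , drop = FALSE]
  grid$score <- NA_real_
  for (i in seq_len(nrow(grid))) {
    res <- dbscan_fit(pts, density_params(grid$eps[i], grid$min_pts[i]))
    grid$score[i] <- if (objective == "ari_vs_labels") {
      adjusted_rand_index(res$labels, labels)
    } else {
      -abs(mean(res$point_type == "border") - target)
    }
  }
  best <- which.max(grid$score)  # first max: smallest eps then min_pts wins ties
  if (prefer_plateau && objective == "ari_vs_labels") {
    eps_levels <- sort(unique(grid$eps))
    near <- grid[grid$score >= max(grid$score) - plateau_tol, , drop = FALSE]
    run_best <- NULL
    for (mp in sort(unique(near$min_pts))) {
      pos <- sort(match(near$eps[near$min_pts == mp], eps_levels))
      run_id <- cumsum(c(1L, diff(pos) != 1L))
      for (r in split(pos, run_id)) {
        if (is.null(run_best) || length(r) > length(run_best$pos)) {
          run_best <- list(pos = r, mp = mp)
        }
      }
    }
    centre <- run_best$pos[ceiling(length(run_best$pos) / 2)]
    best <- which(grid$eps == eps_levels[centre] & grid$min_pts == run_best$mp)
  }
  out <- density_params(grid$eps[best], grid$min_pts[best])
  attr(out, "score") <- grid$score[best]
  attr(out, "grid") <- grid
  out
}

#' Tune a reduction specification per class
#'
#' Builds a [reduction_spec] whose density parameters are grid-tuned
#' independently for each class: the class is compressed to its centroid
#' set and [tune_density_params] selects the (eps, min_pts) cell whose
#' border fraction is closest to `target_border_fraction`. This is the
#' practical entry point when no hand-chosen per-class parameters exist —
#' the border fraction directly controls the retained set size under the
#' `nearest_member` policy (roughly `target * k` rows per class).
#'
#' @param x A [point_set] with class labels.
#' @param per_class_k,alpha Centroid counts, as in [reduction_spec].
#' @param target_border_fraction Desired fraction of border-typed
#'   centroids per class (default 0.5).
#' @param eps_grid Candidate radii; the default spans quantiles of the
#'   nearest-neighbour distances among each class's centroids, adapting
#'   the scale to the data.
#' @param min_pts_grid Candidate density thresholds (default 3:6).
#' @param policy,embed_method,embed_dims,standardize,seed Passed through
#'   to [reduction_spec].
#' @return A [reduction_spec] with per-class `eps` and `min_pts`.
#' @export
tune_reduction_spec <- function(x, per_class_k = NULL, alpha = NULL,
                                target_border_fraction = 0.5,
                                eps_grid = NULL, min_pts_grid = 3:6,
                                policy = "nearest_member",
                                embed_method = "none", embed_dims = NULL,
                                standardize = FALSE, seed = 1L) {
  if (!inherits(x, "point_set") || is.null(x$labels)) {
    stop_invalid("`x` must be a point_set with class labels")
  }
  classes <- sort(unique(x$labels))
  eps_by_class <- list()
  mp_by_class <- list()
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    rows <- which(x$labels == cl)
    n_cl <- length(rows)
    k_cl <- if (!is.null(alpha)) {
      as.integer(ceiling(alpha * n_cl))
    } else {
      as.integer(per_class_value(per_class_k, cl, "per_class_k"))
    }
    k_cl <- min(k_cl, n_cl)
    model <- kmeans_fit(x$points[rows, , drop = FALSE], k = k_cl, seed = seed + ci)
    grid <- eps_grid
    if (is.null(grid)) {
      d <- as.matrix(stats::dist(model$centroids))
      diag(d) <- Inf
      nn <- apply(d, 1L, min)
      grid <- unique(stats::quantile(nn, probs = seq(0.5, 1, by = 0.1)) *
                       c(1, 1.5, 2))
      grid <- grid[grid > 0]
    }
    tuned <- tune_density_params(model$centroids, eps_grid = grid,
                                 min_pts_grid = min_pts_grid,
                                 objective = "border_fraction_target",
                                 target = target_border_fraction)
    key <- as.character(cl)
    eps_by_class[[key]] <- tuned$eps
    mp_by_class[[key]] <- tuned$min_pts
  }
  reduction_spec(per_class_k = per_class_k, alpha = alpha,
                 eps = eps_by_class, min_pts = mp_by_class,
                 embed_method = embed_method, embed_dims = embed_dims,
                 policy = policy, standardize = standardize, seed = seed)
}
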