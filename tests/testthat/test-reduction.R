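test_that("PCA embedding preserves rows and recovers exact subspaces", {
  # points in a 2-D affine subspace of R^4: projection loses nothing
  set.seed(1)
  basis <- qr.Q(qr(matrix(rnorm(8), 4, 2)))
  coords <- matrix(rnorm(60), ncol = 2)
  x <- coords %*% t(basis) + 5
  emb <- embed_points(point_set(x, labels = rep(1:2, 15)), "pca", d_prime = 2)
  expect_equal(nrow(emb$points), 30)
  expect_equal(emb$labels, rep(1:2, 15))
  # pairwise distances are preserved exactly (orthogonal projection onto
  # the data's own plane)
  expect_equal(as.matrix(dist(emb$points)), as.matrix(dist(x)),
               tolerance = 1e-8, ignore_attr = TRUE)

  # top embedded variance equals the leading covariance eigenvalue
  set.seed(2)
  y <- cbind(rnorm(500, sd = 3), rnorm(500, sd = 1), rnorm(500, sd = 0.2))
  emb2 <- embed_points(point_set(y), "pca", d_prime = 1)
  expect_equal(var(emb2$points[, 1]), eigen(cov(y))$values[1], tolerance = 1e-8)

  expect_error(embed_points(point_set(y), "pca", d_prime = 3), "smaller")
  expect_error(embed_points(point_set(y), "umap", d_prime = 2), "not available")
})

test_that("border centroids of a 1-D segment are its two extremes", {
  # 100 equispaced points on [0, 9.9]; with this seed the 10 fitted
  # centroids come out near-equispaced (spacing 0.9-1.1), so with
  # eps = 1.15 (just above the largest spacing) and min_pts = 3 the
  # interior centroids are core (self + 2 neighbours) and only the two
  # extreme centroids are border
  x <- matrix(seq(0, 9.9, by = 0.1), ncol = 1)
  ctr <- sort(kmeans_fit(x, k = 10, seed = 6)$centroids[, 1])
  expect_true(all(diff(ctr) > 0.85 & diff(ctr) < 1.15))
  res <- reduce_class(x, k_c = 10, density_params(eps = 1.15, min_pts = 3),
                      policy = "nearest_member", seed = 6)
  expect_equal(unname(res$stats["n_border"]), 2)
  expect_equal(unname(res$stats["n_core"]), 8)
  expect_length(res$selected, 2)
  # the two selected real points lie in the outermost tenths of the segment
  sel <- x[res$selected, 1]
  expect_true(min(sel) < 1 && max(sel) > 8.9)
})

test_that("degenerate density regimes give empty selections with warnings", {
  x <- matrix(runif(50), ncol = 1)
  # min_pts unattainable at the centroid level -> all noise
  expect_warning(
    res <- reduce_class(x, k_c = 5, density_params(0.01, 6), seed = 1),
    "empty")
  expect_length(res$selected, 0)
  expect_equal(unname(res$stats["n_noise"]), 5)

  # eps beyond the centroid-cloud diameter -> all core, no border
  expect_warning(
    res2 <- reduce_class(x, k_c = 5, density_params(100, 2), seed = 1),
    "empty")
  expect_length(res2$selected, 0)
  expect_equal(unname(res2$stats["n_core"]), 5)
})

test_that("reduction policies obey their containment and typing contracts", {
  blobs <- make_two_blobs(seed = 10)
  base <- list(per_class_k = 20, eps = 1.0, min_pts = 3, seed = 10)
  near <- reduce_dataset(blobs, do.call(reduction_spec, c(base, policy = "nearest_member")))
  all_m <- reduce_dataset(blobs, do.call(reduction_spec, c(base, policy = "all_members")))

  # nearest_member picks one representative per border centroid
  expect_lte(length(near$selected_indices), length(all_m$selected_indices))
  expect_true(all(near$selected_indices %in% all_m$selected_indices))

  # kmeans_only keeps one member per centroid regardless of typing
  km <- reduce_dataset(blobs, do.call(reduction_spec, c(base, policy = "kmeans_only")))
  expect_equal(unname(km$per_class_stats$n_border), c(20, 20))
  expect_lte(length(km$selected_indices), 40)

  for (res in list(near, all_m, km)) {
    # selected rows are real original rows of the right class
    expect_true(all(res$selected_indices %in% seq_len(400)))
    expect_false(any(duplicated(res$selected_indices)))
    expect_identical(res$selected_indices, sort(res$selected_indices))
    expect_equal(res$reduction_ratio, length(res$selected_indices) / 400)
    # typing counts partition the centroids
    st <- res$per_class_stats
    expect_equal(st$n_core + st$n_border + st$n_noise, st$k)
  }
})

test_that("retained points concentrate on the class periphery", {
  moons <- make_two_moons(2000, seed = 12)
  spec <- tune_reduction_spec(moons, per_class_k = 100,
                              target_border_fraction = 0.4, seed = 12)
  red <- reduce_dataset(moons, spec)
  expect_gt(length(red$selected_indices), 0)
  for (cl in 1:2) {
    cls_rows <- which(moons$labels == cl)
    sel_rows <- intersect(red$selected_indices, cls_rows)
    centroid <- colMeans(moons$points[cls_rows, ])
    dist_to_centre <- function(rows)
      mean(sqrt(rowSums(sweep(moons$points[rows, , drop = FALSE], 2, centroid)^2)))
    expect_gt(dist_to_centre(sel_rows), dist_to_centre(cls_rows))
  }
})

test_that("alpha-derived per-class k and clamping behave as specified", {
  blobs <- make_two_blobs(n = 100, seed = 11)
  spec <- reduction_spec(alpha = 0.2, eps = 1.5, min_pts = 2, seed = 11)
  red <- suppressWarnings(reduce_dataset(blobs, spec))
  expect_equal(unname(red$per_class_stats$k), c(10, 10))  # ceiling(0.2 * 50)

  expect_warning(
    withCallingHandlers(
      reduce_class(matrix(rnorm(10), ncol = 2), k_c = 9,
                   density_params(1, 2), seed = 1),
      warning = function(w) {
        if (!grepl("clamped", conditionMessage(w))) invokeRestart("muffleWarning")
      }),
    "clamped")
})

test_that("per-class parameter maps resolve by class label", {
  blobs <- make_two_blobs(seed = 13)
  spec <- reduction_spec(per_class_k = list("1" = 10, "2" = 20),
                         eps = list("1" = 0.8, "2" = 1.2),
                         min_pts = list("1" = 2, "2" = 3), seed = 13)
  red <- suppressWarnings(reduce_dataset(blobs, spec))
  expect_equal(unname(red$per_class_stats$k), c(10, 20))
  expect_error(
    suppressWarnings(
      reduce_dataset(blobs, reduction_spec(per_class_k = list("1" = 10),
                                           eps = 1, min_pts = 2, seed = 1))),
    "per_class_k")
})

test_that("reduce_dataset is deterministic and validates its inputs", {
  blobs <- make_two_blobs(seed = 14)
  spec <- reduction_spec(per_class_k = 15, eps = 1.0, min_pts = 3, seed = 14)
  a <- reduce_dataset(blobs, spec)
  b <- reduce_dataset(blobs, spec)
  expect_identical(a$selected_indices, b$selected_indices)

  unlabelled <- point_set(blobs$points)
  expect_error(reduce_dataset(unlabelled, spec), "labels")
  expect_error(reduction_spec(eps = 1, min_pts = 2), "per_class_k")
  expect_error(reduction_spec(alpha = 1.2, eps = 1, min_pts = 2), "alpha")
  expect_error(reduction_spec(alpha = 0.1, per_class_k = 5, eps = 1, min_pts = 2),
               "exclusive")
})

test_that("grid tuning returns the exhaustive-search optimum with spec tie-breaks", {
  mx <- make_gaussian_mixture(600, seed = 15)
  model <- kmeans_fit(mx, k = 30, seed = 15)
  ctr_lab <- centroid_majority_labels(model, mx$labels)

  # single cell comes straight back
  single <- tune_density_params(model$centroids, 1.3, 3, labels = ctr_lab)
  expect_equal(single$eps, 1.3)
  expect_equal(single$min_pts, 3L)

  eps_grid <- seq(0.6, 2.0, by = 0.2)
  tuned <- tune_density_params(model$centroids, eps_grid, 2:4, labels = ctr_lab)
  grid <- attr(tuned, "grid")
  # full enumeration: no cell beats the returned one
  expect_equal(attr(tuned, "score"), max(grid$score))
  recheck <- vapply(seq_len(nrow(grid)), function(i) {
    r <- dbscan_fit(model$centroids, density_params(grid$eps[i], grid$min_pts[i]))
    adjusted_rand_index(r$labels, ctr_lab)
  }, 0)
  expect_equal(grid$score, recheck)
  # ties break toward smaller eps then smaller min_pts
  winners <- grid[grid$score == max(grid$score), ]
  expect_equal(tuned$eps, min(winners$eps))
  expect_equal(tuned$min_pts, min(winners$min_pts[winners$eps == tuned$eps]))

  expect_error(tune_density_params(model$centroids, numeric(0), 2), "non-empty")
  expect_error(tune_density_params(model$centroids, 1, 2), "labels")
  expect_error(tune_density_params(model$centroids, 1, 2,
                                   objective = "border_fraction_target"),
               "target")
})
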