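test_that("tables round-trip through CSV with labels and full precision", {
  ps <- make_gaussian_mixture(25, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  save_table(ps, path)
  back <- load_table(path, label_col = "label")
  expect_equal(back$points, ps$points, ignore_attr = TRUE)
  expect_equal(back$labels, ps$labels)

  small <- load_table(path)
  expect_equal(ncol(small$points), 3L)  # label column read as a feature
  expect_null(small$labels)

  expect_error(load_table(path, label_col = "class"), "class")
  expect_error(load_table("no/such/file.csv"), "not found")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("f1,f2", "1,2", "x,4"), bad)
  expect_error(load_table(bad), "non-numeric")
})

test_that("bench_config validation catches every field error up front", {
  expect_error(bench_config(list(shape = "hexagon", n = 10), 5, 1, 2), "shape")
  expect_error(bench_config(list(shape = "moons"), 5, 1, 2), "dataset\\$n")
  expect_error(bench_config(list(path = "missing.csv"), 5, 1, 2), "exist")
  expect_error(bench_config(list(shape = "moons", n = 100), 0, 1, 2), "k")
  expect_error(bench_config(list(shape = "moons", n = 100), 5, -1, 2), "eps")
  expect_error(bench_config(list(shape = "moons", n = 100), 5, 1, 0), "min_pts")
  expect_error(bench_config(list(shape = "moons", n = 100), 5, 1, 2,
                            seeds = integer(0)), "seed")
})

test_that("a single-repeat benchmark reports zero spread and is reproducible", {
  cfg <- bench_config(list(shape = "rings", n = 400), k = 40,
                      eps = 1.2, min_pts = 3, seeds = 5)
  rep1 <- run_clustering_benchmark(cfg)
  expect_equal(nrow(rep1$per_seed), 1L)
  expect_true(is.na(rep1$summary$ari_kmdbscan_sd) ||
                rep1$summary$ari_kmdbscan_sd == 0)

  rep2 <- run_clustering_benchmark(cfg)
  timing <- c("time_dbscan", "time_kmdbscan", "speedup")
  expect_identical(rep1$per_seed[, setdiff(names(rep1$per_seed), timing)],
                   rep2$per_seed[, setdiff(names(rep2$per_seed), timing)])
})

test_that("the sensitivity grid emits one row per cell, deterministically", {
  cfg <- bench_config(list(shape = "mixture", n = 300), k = 20,
                      eps = 1, min_pts = 2, seeds = 3)
  single <- run_sensitivity_grid(cfg, eps_grid = 1.2, min_pts_grid = 3)
  expect_equal(nrow(single), 1L)
  expect_equal(single$method, "km_dbscan")

  tab1 <- run_sensitivity_grid(cfg, eps_grid = c(1, 1.2), min_pts_grid = 2:3,
                               include_dbscan = TRUE)
  expect_equal(nrow(tab1), 8L)
  expect_equal(sum(tab1$method == "dbscan"), 4L)
  tab2 <- run_sensitivity_grid(cfg, eps_grid = c(1, 1.2), min_pts_grid = 2:3,
                               include_dbscan = TRUE)
  expect_identical(tab1$ari, tab2$ari)
  expect_error(run_sensitivity_grid(cfg, numeric(0), 2), "non-empty")
})

test_that("the reduction experiment reports one row per policy plus baseline", {
  skip_if_not_installed("e1071")
  blobs <- make_two_blobs(n = 300, seed = 20)
  spec <- tune_reduction_spec(blobs, per_class_k = 15,
                              target_border_fraction = 0.4, seed = 20)
  tab <- run_reduction_experiment(blobs, spec,
                                  policies = c("nearest_member", "kmeans_only"),
                                  seed = 20)
  expect_equal(tab$policy, c("full_data", "nearest_member", "kmeans_only"))
  expect_equal(tab$accuracy_delta[1], 0)
  expect_equal(tab$reduction_ratio[1], 1)
  expect_false(any(tab$failed))
})

test_that("a reduction that keeps every row reproduces the baseline accuracy", {
  skip_if_not_installed("e1071")
  # kmeans_only with k = class size selects every point: the reduced set
  # IS the training set, so the accuracy delta must vanish
  blobs <- make_two_blobs(n = 80, seed = 21)
  spec <- reduction_spec(per_class_k = 40, eps = 1, min_pts = 2,
                         policy = "kmeans_only", seed = 21)
  tab <- suppressWarnings(
    run_reduction_experiment(blobs, spec, policies = "kmeans_only", seed = 21))
  expect_equal(tab$n_train[2], tab$n_train[1])
  expect_equal(tab$accuracy_delta[2], 0)
})

test_that("an empty reduced set is recorded as a failed policy, not an error", {
  skip_if_not_installed("e1071")
  blobs <- make_two_blobs(n = 200, seed = 22)
  # min_pts far above k: every centroid is noise, selection empty
  spec <- reduction_spec(per_class_k = 5, eps = 0.01, min_pts = 50, seed = 22)
  tab <- run_reduction_experiment(blobs, spec, policies = "nearest_member",
                                  seed = 22)
  expect_true(tab$failed[tab$policy == "nearest_member"])
  expect_false(tab$failed[tab$policy == "full_data"])
})
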