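# I/O, configuration validation and the benchmark harness: the repeated
# seeded clustering protocol (mean +/- sd ARI over seeds), a parameter
# sensitivity grid, and the boundary-preservation reduction experiment
# (classifier trained on full vs reduced data). Timing fields are
# informational wall-clock measurements and are never asserted on.

#' Load a feature table from CSV/TSV
#'
#' Reads a delimited table (delimiter inferred from the file extension)
#' into a [point_set]. All non-label columns must be numeric; a parse
#' error names the offending row and column.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file with a header row.
#' @param label_col Optional name of the class-label column.
#' @return A [point_set]; row order matches the file.
#' @export
load_table <- function(path, label_col = NULL) {
  if (!file.exists(path)) stop_invalid(sprintf("file not found: %s", path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  labels <- NULL
  if (!is.null(label_col)) {
    if (!label_col %in% names(df)) {
      stop_invalid(sprintf("label column \"%s\" not found in %s (columns: %s)",
                           label_col, path, paste(names(df), collapse = ", ")))
    }
    labels <- df[[label_col]]
    df[[label_col]] <- NULL
  }
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))))[1L]
      stop_invalid(sprintf("non-numeric feature value in column \"%s\", row %d of %s",
                           names(df)[j], if (is.na(bad)) 1L else bad, path))
    }
  }
  point_set(as.matrix(df), labels = labels)
}

#' Write a point set to CSV
#'
#' Feature columns are named `f1..fd`; labels, when present, go to a
#' `label` column. [load_table] round-trips the result exactly.
#'
#' @param x A [point_set].
#' @param path Output path (`.csv`).
#' @return `path`, invisibly.
#' @export
save_table <- function(x, path) {
  stopifnot(inherits(x, "point_set"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Benchmark configuration
#'
#' Validates the configuration for the benchmark harness up front, so
#' every error is raised with a field-level message before any
#' computation starts.
#'
#' @param dataset Either a generator spec — a list with `shape`
#'   (`"moons"`, `"rings"` or `"mixture"`), `n` and optional generator
#'   arguments — or a list with `path` (+ optional `label_col`) pointing
#'   at a CSV/TSV file.
#' @param k Centroid count for the hybrid stage.
#' @param eps,min_pts Density parameters; either may instead be a grid
#'   (numeric vector), in which case the harness tunes on the first seed.
#' @param seeds Integer vector of RNG seeds, one per repeat.
#' @return An object of class `bench_config`.
#' @export
bench_config <- function(dataset, k, eps, min_pts, seeds = 1:5) {
  if (!is.list(dataset)) stop_invalid("`dataset` must be a list")
  if (!is.null(dataset$path)) {
    if (!file.exists(dataset$path)) {
      stop_invalid(sprintf("dataset$path does not exist: %s", dataset$path))
    }
  } else {
    if (is.null(dataset$shape) ||
        !dataset$shape %in% c("moons", "rings", "mixture")) {
      stop_invalid("dataset$shape must be one of \"moons\", \"rings\", \"mixture\"")
    }
    if (is.null(dataset$n)) stop_invalid("dataset$n is required for a generator spec")
    check_count(dataset$n, "dataset$n", min = 2L)
  }
  k <- check_count(k, "k", min = 1L)
  if (!is.numeric(eps) || length(eps) < 1L || any(eps <= 0)) {
    stop_invalid("`eps` must be one or more positive values")
  }
  if (!is.numeric(min_pts) || length(min_pts) < 1L || any(min_pts < 1)) {
    stop_invalid("`min_pts` must be one or more integers >= 1")
  }
  if (length(seeds) < 1L) stop_invalid("at least one seed is required")
  structure(list(dataset = dataset, k = k, eps = as.numeric(eps),
                 min_pts = as.integer(min_pts), seeds = as.integer(seeds)),
            class = "bench_config")
}

bench_dataset <- function(config, seed) {
  ds <- config$dataset
  if (!is.null(ds$path)) return(load_table(ds$path, ds$label_col))
  switch(ds$shape,
    moons = make_two_moons(ds$n,
                           noise_sd = if (is.null(ds$noise_sd)) 0.1 else ds$noise_sd,
                           seed = seed),
    rings = make_concentric_rings(ds$n,
                                  radii = if (is.null(ds$radii)) c(1, 3) else ds$radii,
                                  noise_sd = if (is.null(ds$noise_sd)) 0.05 else ds$noise_sd,
                                  seed = seed),
    mixture = {
      args <- list(n = ds$n, seed = seed)
      if (!is.null(ds$means)) args$means <- ds$means
      if (!is.null(ds$sds)) args$sds <- ds$sds
      do.call(make_gaussian_mixture, args)
    }
  )
}

# Majority ground-truth label of the points assigned to each centroid;
# used to tune centroid-level density parameters against ground truth.
#' Majority ground-truth label per centroid
#'
#' For each centroid of a fitted model, the most frequent ground-truth
#' label among its assigned points — the centroid-level ground truth used
#' when grid-tuning density parameters against labels.
#'
#' @param model A `centroid_model`.
#' @param labels Ground-truth labels of the original points.
#' @return Integer vector of length `model$k`.
#' @export
centroid_majority_labels <- function(model, labels) {
  stopifnot(inherits(model, "centroid_model"),
            length(labels) == length(model$assignment))
  labels <- as.integer(labels)
  vapply(seq_len(model$k), function(j) {
    tab <- table(labels[model$assignment == j])
    as.integer(names(tab)[which.max(tab)])
  }, integer(1))
}

#' Repeated seeded clustering benchmark
#'
#' For each seed: generate (or load) the dataset, run plain DBSCAN on the
#' full data and KM-DBSCAN with `k` centroids, and score both against the
#' ground-truth labels with the adjusted Rand index. When `eps` /
#' `min_pts` are grids, the density parameters are grid-tuned for each
#' seed's dataset at the centroid level (exhaustive search maximising the
#' ARI against the centroids' majority ground-truth labels), mirroring
#' per-dataset empirical tuning. Reports per-seed values and
#' mean +/- sd aggregates; the clustering-style reduction ratio reported
#' here is k / n (centroids per point).
#'
#' @param config A [bench_config] whose dataset carries ground-truth
#'   labels.
#' @return An object of class `bench_report` with `per_seed` (data frame)
#'   and `summary` (list of means and sds).
#' @export
run_clustering_benchmark <- function(config) {
  stopifnot(inherits(config, "bench_config"))
  tune <- length(config$eps) > 1L || length(config$min_pts) > 1L
  params <- if (!tune) density_params(config$eps, config$min_pts) else NULL
  rows <- vector("list", length(config$seeds))
  for (i in seq_along(config$seeds)) {
    s <- config$seeds[i]
    ps <- bench_dataset(config, s)
    if (is.null(ps$labels)) stop_invalid("benchmark dataset must carry ground-truth labels")
    n <- n_points(ps)

    if (tune) {
      model <- kmeans_fit(ps, k = config$k, seed = s)
      ctr_labels <- centroid_majority_labels(model, ps$labels)
      params <- tune_density_params(model$centroids,
                                    eps_grid = config$eps,
                                    min_pts_grid = config$min_pts,
                                    objective = "ari_vs_labels",
                                    labels = ctr_labels,
                                    prefer_plateau = TRUE)
    }

    t0 <- proc.time()[["elapsed"]]
    full <- dbscan_fit(ps, params)
    t_full <- proc.time()[["elapsed"]] - t0

    t0 <- proc.time()[["elapsed"]]
    hybrid <- km_dbscan(ps, k = config$k, params = params, seed = s)
    t_hybrid <- proc.time()[["elapsed"]] - t0

    rows[[i]] <- data.frame(
      seed = s,
      eps = params$eps,
      min_pts = params$min_pts,
      ari_dbscan = adjusted_rand_index(full$labels, ps$labels),
      ari_kmdbscan = adjusted_rand_index(hybrid$point_labels, ps$labels),
      reduction_ratio = config$k / n,
      time_dbscan = t_full,
      time_kmdbscan = t_hybrid,
      speedup = if (t_hybrid > 0) t_full / t_hybrid else NA_real_
    )
  }
  per_seed <- do.call(rbind, rows)
  structure(list(
    per_seed = per_seed,
    params = params,
    summary = list(
      ari_kmdbscan_mean = mean(per_seed$ari_kmdbscan),
      ari_kmdbscan_sd = stats::sd(per_seed$ari_kmdbscan),
      ari_dbscan_mean = mean(per_seed$ari_dbscan),
      ari_dbscan_sd = stats::sd(per_seed$ari_dbscan),
      reduction_ratio = per_seed$reduction_ratio[1L],
      n_seeds = nrow(per_seed)
    )
  ), class = "bench_report")
}

#' @export
print.bench_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "bench_report over %d seed(s): KM-DBSCAN ARI %.4f +/- %.4f | DBSCAN ARI %.4f +/- %.4f | reduction ratio %.4f\n",
    s$n_seeds, s$ari_kmdbscan_mean, s$ari_kmdbscan_sd,
    s$ari_dbscan_mean, s$ari_dbscan_sd, s$reduction_ratio))
  invisible(x)
}

#' Parameter-sensitivity grid
#'
#' Evaluates DBSCAN and/or KM-DBSCAN over every (eps, min_pts, k) cell on
#' one fixed seeded dataset, one row per cell, for assessing how stable
#' the ARI is under parameter perturbation.
#'
#' @param config A [bench_config]; its first seed fixes the dataset.
#' @param eps_grid,min_pts_grid Non-empty parameter grids.
#' @param k_grid Centroid counts for KM-DBSCAN rows (default the config
#'   `k`); use `NULL` to skip the hybrid.
#' @param include_dbscan Also evaluate plain DBSCAN on the full data per
#'   (eps, min_pts) cell (default `FALSE`; quadratic in n).
#' @return Data frame with columns method, k, eps, min_pts, ari, time_s.
#' @export
run_sensitivity_grid <- function(config, eps_grid, min_pts_grid,
                                 k_grid = NULL, include_dbscan = FALSE) {
  stopifnot(inherits(config, "bench_config"))
  if (length(eps_grid) == 0L || length(min_pts_grid) == 0L) {
    stop_invalid("`eps_grid` and `min_pts_grid` must be non-empty")
  }
  if (is.null(k_grid)) k_grid <- config$k
  seed <- config$seeds[1L]
  ps <- bench_dataset(config, seed)
  if (is.null(ps$labels)) stop_invalid("sensitivity grid requires ground-truth labels")

  rows <- list()
  if (include_dbscan) {
    for (e in eps_grid) for (mp in min_pts_grid) {
      t0 <- proc.time()[["elapsed"]]
      res <- dbscan_fit(ps, density_params(e, mp))
      rows[[length(rows) + 1L]] <- data.frame(
        method = "dbscan", k = NA_integer_, eps = e, min_pts = mp,
        ari = adjusted_rand_index(res$labels, ps$labels),
        time_s = proc.time()[["elapsed"]] - t0)
    }
  }
  for (k in k_grid) {
    model <- kmeans_fit(ps, k = k, seed = seed)
    for (e in eps_grid) for (mp in min_pts_grid) {
      t0 <- proc.time()[["elapsed"]]
      ctr <- dbscan_fit(model$centroids, density_params(e, mp))
      lab <- propagate_labels(model, ctr$labels)
      rows[[length(rows) + 1L]] <- data.frame(
        method = "km_dbscan", k = k, eps = e, min_pts = mp,
        ari = adjusted_rand_index(lab, ps$labels),
        time_s = proc.time()[["elapsed"]] - t0)
    }
  }
  do.call(rbind, rows)
}

#' SVM adapter
#'
#' Thin wrapper over [e1071::svm] (RBF kernel) exposing test accuracy,
#' the support-vector count and the training time, for the
#' boundary-preservation experiment.
#'
#' @param train,test [point_set]s with class labels.
#' @param cost,gamma SVM hyperparameters (`gamma = NULL` uses the e1071
#'   default 1/d).
#' @return List: `accuracy`, `n_sv`, `train_time_s`, `model`.
#' @export
svm_adapter <- function(train, test, cost = 1, gamma = NULL) {
  if (!requireNamespace("e1071", quietly = TRUE)) {
    stop_invalid("the SVM adapter requires the e1071 package")
  }
  stopifnot(inherits(train, "point_set"), inherits(test, "point_set"))
  if (is.null(train$labels) || is.null(test$labels)) {
    stop_invalid("train and test sets must carry class labels")
  }
  args <- list(x = train$points, y = factor(train$labels),
               kernel = "radial", cost = cost, scale = FALSE)
  if (!is.null(gamma)) args$gamma <- gamma
  t0 <- proc.time()[["elapsed"]]
  fit <- do.call(e1071::svm, args)
  t_train <- proc.time()[["elapsed"]] - t0
  pred <- stats::predict(fit, test$points)
  list(accuracy = mean(as.character(pred) == as.character(test$labels)),
       n_sv = nrow(fit$SV),
       train_time_s = t_train,
       model = fit)
}

#' Boundary-preservation reduction experiment
#'
#' Splits a labelled dataset into train/test, trains the downstream
#' classifier on the full training set and on each requested reduction
#' policy, and reports per-policy accuracy, accuracy delta vs the full
#' baseline, reduction ratio, support-vector ratio and train-time
#' speedup. A policy whose reduced set is empty is recorded as failed and
#' the run continues.
#'
#' @param x A [point_set] with class labels.
#' @param spec A [reduction_spec]; its `policy` field is overridden per
#'   row by `policies`.
#' @param policies Character vector of policies to evaluate.
#' @param test_fraction Held-out fraction (default 0.3).
#' @param seed Integer RNG seed for the split.
#' @param cost,gamma Passed to [svm_adapter].
#' @return Data frame with one row for the full-data baseline and one per
#'   policy.
#' @export
run_reduction_experiment <- function(x, spec,
                                     policies = c("nearest_member",
                                                  "kmeans_only",
                                                  "dbscan_only"),
                                     test_fraction = 0.3,
                                     seed = 1L, cost = 1, gamma = NULL) {
  stopifnot(inherits(x, "point_set"), inherits(spec, "reduction_spec"))
  if (is.null(x$labels)) stop_invalid("`x` must carry class labels")
  n <- n_points(x)
  idx_test <- with_seed(seed, sample.int(n, size = max(1L, round(test_fraction * n))))
  idx_train <- setdiff(seq_len(n), idx_test)
  train <- point_set(x$points[idx_train, , drop = FALSE], x$labels[idx_train])
  test <- point_set(x$points[idx_test, , drop = FALSE], x$labels[idx_test])

  base <- svm_adapter(train, test, cost = cost, gamma = gamma)
  rows <- list(data.frame(
    policy = "full_data", n_train = n_points(train), accuracy = base$accuracy,
    accuracy_delta = 0, reduction_ratio = 1,
    sv_ratio = 1, speedup = 1, failed = FALSE))

  for (pol in policies) {
    sp <- spec
    sp$policy <- pol
    red <- withCallingHandlers(
      reduce_dataset(train, sp),
      warning = function(w) invokeRestart("muffleWarning"))
    if (length(red$selected_indices) == 0L ||
        length(unique(train$labels[red$selected_indices])) < 2L) {
      rows[[length(rows) + 1L]] <- data.frame(
        policy = pol, n_train = 0L, accuracy = NA_real_,
        accuracy_delta = NA_real_, reduction_ratio = 0,
        sv_ratio = NA_real_, speedup = NA_real_, failed = TRUE)
      next
    }
    red_train <- point_set(train$points[red$selected_indices, , drop = FALSE],
                           train$labels[red$selected_indices])
    fit <- svm_adapter(red_train, test, cost = cost, gamma = gamma)
    rows[[length(rows) + 1L]] <- data.frame(
      policy = pol, n_train = n_points(red_train), accuracy = fit$accuracy,
      accuracy_delta = fit$accuracy - base$accuracy,
      reduction_ratio = red$reduction_ratio,
      sv_ratio = fit$n_sv / base$n_sv,
      speedup = if (fit$train_time_s > 0) base$train_time_s / fit$train_time_s else NA_real_,
      failed = FALSE)
  }
  do.call(rbind, rows)
}
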